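make_note <- function(id, pid, date, n_tokens = 60) {
  data.frame(note_id = id, patient_id = pid, encounter_date = date,
             text = paste(rep("word", n_tokens), collapse = " "),
             stringsAsFactors = FALSE)
}

test_that("each filter removes exactly the offending records, in order", {
  orders <- data.frame(
    patient_id = c("A", "A", "A", "A", "B"),
    encounter_date = c(0, 100, 100, 200, 0),
    start_date = c(0, 100, 100, NA, 0),
    drug_name = c("norethindrone 0.35 mg oral tablet",
                  "etonogestrel-ethinyl estradiol vaginal ring",
                  "etonogestrel-ethinyl estradiol vaginal ring",
                  "norethindrone 0.35 mg oral tablet",
                  "levonorgestrel 1.5 mg tablet (emergency)"),
    therapeutic_class = "CONTRACEPTIVES", stringsAsFactors = FALSE)
  notes <- rbind(make_note("n1", "A", 0), make_note("n2", "A", 100),
                 make_note("n3", "A", 400), make_note("n4", "B", 0))
  res <- apply_filters(orders, notes)
  att <- res$attrition
  expect_equal(att$removed[att$filter == "excluded_pattern"], 1)  # emergency
  expect_equal(att$removed[att$filter == "missing_start"], 1)
  expect_equal(att$removed[att$filter == "duplicate"], 1)
  # B's only order was excluded; A has follow-up via the day-400 note
  expect_equal(sort(unique(res$orders$patient_id)), "A")
  expect_equal(nrow(res$orders), 2)
  expect_true(all(res$orders$modality %in% modality_levels()))
  expect_equal(res$orders$note_id, c("n1", "n2"))
})

test_that("attrition counts are conserved along the filter sequence", {
  cfg <- sim_config(n_patients = 80, switch_probability = 0.3, seed = 21,
                    noise_rates = list(missing_start = 0.1, duplicate = 0.1,
                                       missing_note = 0.05, short_note = 0.05,
                                       lost_followup = 0.1,
                                       non_contraceptive = 0.1,
                                       emergency = 0.05))
  sim <- generate_cohort(cfg)
  att <- apply_filters(sim$orders, sim$notes)$attrition
  expect_true(all(diff(att$remaining) <= 0))
  expect_equal(att$remaining[-1],
               utils::head(att$remaining, -1) - att$removed[-1])
  expect_true(all(att$removed >= 0))
})

test_that("attrition equals the generator's planted per-filter counts", {
  cfg <- sim_config(n_patients = 200, switch_probability = 0.3, seed = 13,
                    noise_rates = list(missing_start = 0.05, duplicate = 0.07,
                                       missing_note = 0.04, short_note = 0.03,
                                       lost_followup = 0.06,
                                       non_contraceptive = 0.08,
                                       emergency = 0.02))
  sim <- generate_cohort(cfg)
  att <- apply_filters(sim$orders, sim$notes)$attrition
  planted <- sim$truth$filter_removals
  observed <- att$removed[match(names(planted), att$filter)]
  expect_equal(unname(observed), unname(planted))
})

test_that("unmapped drug names are dropped with a warning", {
  orders <- data.frame(patient_id = "A", encounter_date = 0, start_date = 0,
                       drug_name = "mystery compound xyz",
                       therapeutic_class = "CONTRACEPTIVES",
                       stringsAsFactors = FALSE)
  notes <- make_note("n1", "A", 0)
  expect_warning(res <- apply_filters(orders, notes), "unmapped")
  expect_equal(res$attrition$removed[res$attrition$filter == "unmapped"], 1)
})

test_that("schema violations name the offending column", {
  expect_error(apply_filters(data.frame(patient_id = "A"), make_note("n", "A", 0)),
               "encounter_date")
})

test_that("switch detection emits set differences between consecutive encounters", {
  same <- timeline_to_orders(list(list(date = 0, modalities = "Oral"),
                                  list(date = 90, modalities = "Oral")))
  expect_equal(nrow(detect_switches(same)), 0)

  one <- timeline_to_orders(list(list(date = 0, modalities = "Oral"),
                                 list(date = 90, modalities = "Intravaginal")))
  ev <- detect_switches(one)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$stopped, "Oral")
  expect_equal(ev$started, "Intravaginal")

  back <- timeline_to_orders(list(list(date = 0, modalities = "Oral"),
                                  list(date = 90, modalities = "IUD"),
                                  list(date = 180, modalities = "Oral")))
  expect_equal(nrow(detect_switches(back)), 2)

  multi <- timeline_to_orders(list(
    list(date = 0, modalities = c("Oral", "Transdermal")),
    list(date = 90, modalities = c("Oral", "IUD"))))
  ev <- detect_switches(multi)
  expect_equal(ev$stopped, "Transdermal")
  expect_equal(ev$started, "IUD")
})

test_that("switch detection matches the exhaustive pairwise oracle", {
  set.seed(77)
  for (rep in 1:200) {
    tl <- random_timeline(sample(2:6, 1))
    got <- detect_switches(timeline_to_orders(tl))
    want <- brute_force_switches(tl)
    expect_equal(nrow(got), length(want))
    for (j in seq_along(want)) {
      expect_equal(got$stopped[j],
                   paste(sort(want[[j]]$stopped), collapse = ";"))
      expect_equal(got$started[j],
                   paste(sort(want[[j]]$started), collapse = ";"))
    }
  }
})

test_that("no event stops and starts the same modality; reversal swaps roles", {
  set.seed(5)
  for (rep in 1:50) {
    tl <- random_timeline(sample(2:5, 1))
    fwd <- detect_switches(timeline_to_orders(tl))
    for (j in seq_len(nrow(fwd))) {
      expect_length(intersect(strsplit(fwd$stopped[j], ";")[[1]],
                              strsplit(fwd$started[j], ";")[[1]]), 0)
    }
    rev_tl <- rev(tl)
    for (j in seq_along(rev_tl)) rev_tl[[j]]$date <- j * 30L
    bwd <- detect_switches(timeline_to_orders(rev_tl))
    expect_equal(nrow(bwd), nrow(fwd))
    if (nrow(fwd)) {
      expect_equal(bwd$stopped, rev(fwd$started))
      expect_equal(bwd$started, rev(fwd$stopped))
    }
  }
})

test_that("unsorted timelines are rejected when sortedness is asserted", {
  o <- timeline_to_orders(list(list(date = 90, modalities = "Oral"),
                               list(date = 0, modalities = "IUD")))
  o <- o[order(-o$start_date), ]
  expect_error(detect_switches(o, check_sorted = TRUE), "sorted")
})

test_that("switchers detected on noise-free data equal the planted count", {
  sim <- generate_cohort(sim_config(n_patients = 150,
                                    switch_probability = 0.25, seed = 31))
  fl <- apply_filters(sim$orders, sim$notes)
  sw <- detect_switches(fl$orders)
  expect_equal(length(unique(sw$patient_id)), sim$truth$n_switch_patients)
  expect_equal(nrow(sw), sim$truth$n_switch_events)
  m <- switch_matrix(sw)
  expect_equal(sum(m), nrow(sw))
})

test_that("demographic comparison reproduces closed-form statistics", {
  a <- data.frame(age_first_rx = c(20, 25, 30),
                  race_ethnicity = c("White", "Asian", "White"),
                  preferred_language = "English", stringsAsFactors = FALSE)
  b <- a
  cmp <- demographic_comparison(a, b)
  expect_equal(cmp$age_first_rx$statistic, 0)
  expect_equal(cmp$age_first_rx$p_value, 1)
  # perfectly homogeneous 2x2 -> chi-square 0
  a2 <- data.frame(age_first_rx = rnorm(20),
                   race_ethnicity = rep(c("White", "Asian"), each = 10),
                   preferred_language = "English", stringsAsFactors = FALSE)
  cmp2 <- demographic_comparison(a2, a2)
  expect_equal(cmp2$race_ethnicity$statistic, 0)
  # constant categorical in both groups -> not applicable
  expect_false(cmp2$preferred_language$applicable)
  expect_error(demographic_comparison(a[0, ], b), "non-empty")
})

test_that("chi-square matches the textbook expected-count formula on a 2x3 table", {
  counts <- matrix(c(10, 20, 30, 15, 10, 35), nrow = 2, byrow = TRUE)
  a <- data.frame(age_first_rx = 1,
                  race_ethnicity = rep(c("X", "Y", "Z"), counts[1, ]),
                  stringsAsFactors = FALSE)
  b <- data.frame(age_first_rx = 1,
                  race_ethnicity = rep(c("X", "Y", "Z"), counts[2, ]),
                  stringsAsFactors = FALSE)
  cmp <- demographic_comparison(a, b, continuous = character(0),
                                categorical = "race_ethnicity")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  expect_equal(cmp$race_ethnicity$statistic, stat, tolerance = 1e-12)
  expect_equal(cmp$race_ethnicity$df, 2)
})
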