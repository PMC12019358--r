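test_that("regeneration with a fixed seed is identical", {
  cfg <- sim_config(n_patients = 60, switch_probability = 0.3, seed = 42,
                    noise_rates = list(missing_start = 0.05, duplicate = 0.05))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$orders, b$orders)
  expect_identical(a$notes, b$notes)
  expect_identical(a$gold, b$gold)
  expect_identical(a$truth, b$truth)
})

test_that("generation leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  generate_cohort(sim_config(n_patients = 10, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("zero switch probability yields no switches end to end", {
  sim <- generate_cohort(sim_config(n_patients = 50, switch_probability = 0,
                                    seed = 7))
  expect_equal(sim$truth$n_switch_events, 0)
  expect_true(all(is.na(sim$gold$true_stopped)))
  fl <- apply_filters(sim$orders, sim$notes)
  expect_equal(nrow(detect_switches(fl$orders)), 0)
})

test_that("planted-truth counts survive an independent recount of the tables", {
  cfg <- sim_config(n_patients = 150, switch_probability = 0.4, seed = 11,
                    noise_rates = list(missing_start = 0.06, duplicate = 0.08,
                                       missing_note = 0.04, short_note = 0.03,
                                       non_contraceptive = 0.05,
                                       emergency = 0.02))
  sim <- generate_cohort(cfg)
  tr <- sim$truth
  # switches: recount from gold
  expect_equal(sum(!is.na(sim$gold$true_stopped)), tr$n_switch_events)
  # missing start dates: recount from orders
  expect_equal(sum(is.na(sim$orders$start_date)),
               tr$filter_removals[["missing_start"]])
  # duplicates: recount duplicated (patient, date, drug) keys
  key <- paste(sim$orders$patient_id, sim$orders$encounter_date,
               sim$orders$drug_name)
  expect_equal(sum(duplicated(key)), tr$filter_removals[["duplicate"]])
  # distractor rows: recount by class / emergency pattern
  expect_equal(sum(sim$orders$therapeutic_class == "ANALGESICS"),
               tr$filter_removals[["non_contraceptive"]])
  expect_equal(sum(grepl("emergency", sim$orders$drug_name)),
               tr$filter_removals[["excluded_pattern"]])
  # short notes: recount by token count among non-followup encounter notes
  expect_equal(sum(switchscope:::count_tokens(sim$notes$text) <=
                     cfg$note_token_threshold),
               tr$filter_removals[["short_note"]])
  # per-(topic, subgroup) counts: recount from gold x demographics
  g <- sim$gold[!is.na(sim$gold$true_reason_topic), ]
  pats <- sim$notes$patient_id[match(g$note_id, sim$notes$note_id)]
  race <- sim$demographics$race_ethnicity[match(pats,
                                                sim$demographics$patient_id)]
  recount <- table(g$true_reason_topic, race)
  tsc <- tr$topic_subgroup_counts
  tsc <- tsc[tsc$axis == "race_ethnicity", ]
  for (i in seq_len(nrow(tsc))) {
    expect_equal(unname(recount[tsc$topic[i], tsc$subgroup[i]]), tsc$n[i])
  }
})

test_that("notes exceed the token threshold unless flagged short", {
  long <- generate_note(stopped_mention = "Camila",
                        started_mention = "NuvaRing", reason = "spotting")
  expect_gt(length(strsplit(long, "\\s+")[[1]]), 50)
  short <- generate_note(short_note = TRUE)
  expect_lte(length(strsplit(short, "\\s+")[[1]]), 50)
  # switch notes carry both modality cues and the reason phrase
  expect_match(long, "stopped Camila")
  expect_match(long, "starting NuvaRing")
  expect_match(long, "because spotting")
})

test_that("redaction replaces person-name-like brands with a placeholder", {
  txt <- generate_note(stopped_mention = "Camila",
                       started_mention = "NuvaRing",
                       reason = "spotting", redact = TRUE)
  expect_match(txt, "\\[REDACTED\\]", all = FALSE)
  expect_no_match(txt, "Camila")
  expect_error(generate_note(stopped_mention = c("a", "b")), "at most one")
})

test_that("invalid configurations are rejected", {
  bad_dist <- c(Oral = 0.5, Implant = 0.5, IUD = 0.5, Injectable = 0,
                Transdermal = 0, Intravaginal = 0)
  expect_error(sim_config(modality_start_distribution = bad_dist), "sum to 1")
  expect_error(sim_config(noise_rates = list(duplicate = 1.5)), "\\[0, 1\\]")
  expect_error(sim_config(noise_rates = list(bogus = 0.1)), "unknown noise")
  expect_error(sim_config(switch_probability = -0.1), "\\[0, 1\\]")
  cat_bad <- list(list(topic = "empty", adverse_event = FALSE,
                       phrases = character(0)))
  expect_error(sim_config(reason_topic_catalog = cat_bad), "empty phrase")
  plan_bad <- data.frame(topic = "nope", subgroup = "White", factor = 2)
  expect_error(sim_config(subgroup_enrichment_plan = plan_bad),
               "unknown topics")
})

test_that("written cohort files round-trip", {
  sim <- generate_cohort(sim_config(n_patients = 15, switch_probability = 0.5,
                                    seed = 3))
  dir <- withr::local_tempdir()
  write_synthetic_cohort(sim, dir)
  orders <- read.csv(file.path(dir, "orders.csv"))
  expect_equal(nrow(orders), nrow(sim$orders))
  notes <- read_notes_jsonl(file.path(dir, "notes.jsonl"))
  expect_equal(notes$text, sim$notes$text)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$n_switch_events, sim$truth$n_switch_events)
})
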