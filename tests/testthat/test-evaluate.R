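test_that("micro F1 pools TP/FP/FN over positive labels", {
  gold <- c("Oral", "IUD", "Oral")
  expect_equal(micro_f1(gold, gold)[["f1"]], 1.0)
  res <- micro_f1(c("Oral", "Oral", NA), gold)
  expect_equal(unname(res[c("tp", "fp", "fn")]), c(1, 1, 2))
  expect_equal(res[["precision"]], 0.5)
  expect_equal(res[["recall"]], 1 / 3)
  expect_equal(res[["f1"]], 0.4)
  expect_equal(micro_f1(c(NA, NA, NA), gold)[["f1"]], 0)
  expect_error(micro_f1("Oral", gold), "equal length")
})

test_that("micro F1 is permutation invariant and exact only at agreement", {
  set.seed(3)
  labs <- c(modality_levels(), NA)
  for (rep in 1:20) {
    pred <- sample(labs, 30, TRUE)
    gold <- sample(labs, 30, TRUE)
    perm <- sample(30)
    expect_equal(micro_f1(pred, gold), micro_f1(pred[perm], gold[perm]))
    pos <- !is.na(gold)
    agrees <- all(is.na(pred) == is.na(gold)) &&
      all(pred[pos] == gold[pos]) && any(pos)
    expect_equal(micro_f1(pred, gold)[["f1"]] == 1, agrees)
  }
})

test_that("kappa hits its closed-form anchors", {
  a <- c(rep("x", 5), rep("y", 5))
  expect_equal(cohens_kappa(a, a), 1.0)
  # 2x2 table [[5,5],[5,5]]: observed = expected agreement
  b <- c(rep(c("x", "y"), each = 5))
  a2 <- rep(c("x", "y"), 5)
  tab <- table(a2, b)
  expect_true(all(tab == 5) || sum(tab) == 10)
  expect_equal(cohens_kappa(rep(c("x", "x", "y", "y"), 5),
                            rep(c("x", "y", "x", "y"), 5)), 0)
  # balanced perfect disagreement
  expect_equal(cohens_kappa(c("x", "y", "x", "y"), c("y", "x", "y", "x")), -1)
  expect_true(is.na(cohens_kappa(rep("x", 4), rep("x", 4))))  # p_e = 1
})

test_that("kappa is symmetric and relabeling-invariant; agrees with e1071", {
  skip_if_not_installed("e1071")
  set.seed(8)
  for (rep in 1:20) {
    a <- sample(c("Oral", "IUD", NA), 40, TRUE)
    b <- sample(c("Oral", "IUD", NA), 40, TRUE)
    k <- cohens_kappa(a, b)
    expect_equal(k, cohens_kappa(b, a))
    relab <- c(Oral = "Z1", IUD = "Z2")
    a2 <- ifelse(is.na(a), NA, relab[a])
    b2 <- ifelse(is.na(b), NA, relab[b])
    expect_equal(cohens_kappa(a2, b2), k)
    # independent oracle on the same contingency table
    tab <- table(ifelse(is.na(a), ".none", a), ifelse(is.na(b), ".none", b))
    expect_equal(k, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("restricting to relevant notes drops none-reference pairs first", {
  a <- c("Oral", NA, "IUD", NA, "Oral")
  b <- c("Oral", "Oral", "IUD", NA, "IUD")
  full <- cohens_kappa(a, b)
  restr <- cohens_kappa(a, b, restrict_to_relevant = TRUE)
  expect_equal(restr, cohens_kappa(a[!is.na(a)], b[!is.na(a)]))
  expect_false(isTRUE(all.equal(full, restr)))
  expect_true(is.na(cohens_kappa(c(NA, NA), c("Oral", "IUD"),
                                 restrict_to_relevant = TRUE)))
})

test_that("human evaluation report computes rates over annotated notes", {
  ex <- data.frame(note_id = sprintf("n%02d", 1:93),
                   stopped = "Oral", started = "IUD", reason = "spotting",
                   stringsAsFactors = FALSE)
  ann <- data.frame(note_id = ex$note_id,
                    gold_stopped = "Oral", gold_started = "IUD",
                    reason_accurate = TRUE,
                    hallucination = c(rep(TRUE, 2), rep(FALSE, 91)),
                    stringsAsFactors = FALSE)
  rep <- human_eval_report(ex, ann)
  expect_equal(rep$n, 93)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$hallucination_rate, 2 / 93, tolerance = 1e-12)
  expect_equal(rep$started[["f1"]], 1.0)
  # accuracy + error fraction = 1 on fully annotated input
  ann$reason_accurate <- c(rep(FALSE, 10), rep(TRUE, 83))
  rep2 <- human_eval_report(ex, ann)
  expect_equal(rep2$accuracy + 10 / 93, 1.0, tolerance = 1e-12)
  # missing booleans leave the denominator (flags sit at positions 1:2)
  ann$hallucination[3:5] <- NA
  expect_equal(human_eval_report(ex, ann)$hallucination_rate, 2 / 90,
               tolerance = 1e-12)
  expect_error(human_eval_report(ex, transform(ann, note_id = paste0("z", note_id))),
               "no overlapping")
})

test_that("learning curve reaches F1 = 1 on separable notes and degrades with data", {
  uniform <- setNames(rep(1 / 6, 6), modality_levels())
  sim <- generate_cohort(sim_config(n_patients = 260, switch_probability = 1,
                                    encounters_range = c(2L, 2L),
                                    modality_start_distribution = uniform,
                                    seed = 23))
  g <- sim$gold[!is.na(sim$gold$true_started), ]
  texts <- sim$notes$text[match(g$note_id, sim$notes$note_id)]
  lc <- learning_curve(texts, g$true_started, fractions = c(1, 0.25),
                       k = 2L, seed = 4L)
  expect_equal(lc$mean_f1[lc$fraction == 1], 1.0, tolerance = 1e-9)
  expect_gte(lc$mean_f1[lc$fraction == 1], lc$mean_f1[lc$fraction == 0.25])
  # a subsample too small to contain every class skips the fold with a warning
  expect_warning(
    tiny <- learning_curve(texts, g$true_started, fractions = 0.02,
                           k = 1L, seed = 4L),
    "class missing")
  expect_equal(tiny$n_folds, 0)
  expect_equal(nrow(learning_curve(texts, g$true_started,
                                   fractions = numeric(0))), 0)
  expect_error(learning_curve(texts, g$true_started, fractions = c(0, 1)),
               "fractions")
})
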