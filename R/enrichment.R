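#' Build a subgroup indicator matrix from demographics
#'
#' Stratifies notes into patient subgroups along one axis. The
#' race/ethnicity axis uses the self-reported categories verbatim (White,
#' Latinx, Black or African American, Asian, Other, Multi-Race/Ethnicity;
#' unknown values are logged and binned as Other). The age axis uses the
#' bins `<21` (age < 21), `21-30` (21 <= age <= 30), `31-40`
#' (31 <= age <= 40) and `40+` (age > 40); 40 falls in `31-40` by the
#' closed-interval convention documented here, since the nominal bins touch
#' at 40. Notes whose patient has missing demographics on the axis are
#' excluded (all-zero row).
#'
#' @param note_patients Character vector: patient id per note.
#' @param demographics Demographics data frame (`patient_id`,
#'   `race_ethnicity`, `age_first_rx`).
#' @param axis `"race_ethnicity"` or `"age"`.
#' @return Binary matrix, notes by subgroups, with at most one 1 per row.
#' @export
stratify <- function(note_patients, demographics,
                     axis = c("race_ethnicity", "age")) {
  axis <- match.arg(axis)
  check_columns(demographics, c("patient_id"), "demographics")
  idx <- match(note_patients, demographics$patient_id)
  if (axis == "race_ethnicity") {
    levels <- c("White", "Latinx", "Black or African American", "Asian",
                "Other", "Multi-Race/Ethnicity")
    val <- demographics$race_ethnicity[idx]
    unknown <- !is.na(val) & !val %in% levels
    if (any(unknown)) {
      message(sum(unknown), " note(s) with unrecognized race/ethnicity ",
              "binned as Other")
      val[unknown] <- "Other"
    }
  } else {
    levels <- c("<21", "21-30", "31-40", "40+")
    age <- demographics$age_first_rx[idx]
    val <- ifelse(is.na(age), NA_character_, .age_bin(age))
  }
  y <- matrix(0L, length(note_patients), length(levels),
              dimnames = list(NULL, levels))
  ok <- which(!is.na(val))
  y[cbind(ok, match(val[ok], levels))] <- 1L
  y
}

#' Topic-by-subgroup enrichment scores
#'
#' For topic weights `q` (notes x topics, rows summing to 1) and a binary
#' subgroup indicator `y` (notes x subgroups), the enrichment of topic `k`
#' in subgroup `j` is
#' \deqn{\theta_{k,j} = N \frac{\sum_n q_{n,k} y_{n,j}}
#'   {\sum_n q_{n,k} \sum_n y_{n,j}}}
#' i.e. the joint topic-subgroup weight normalized by total topic weight and
#' subgroup size, scaled by the note count `N` so that independence of
#' topics and subgroups gives \eqn{\theta = 1}. Reported scores are natural
#' logs; cells with a zero denominator are `NA` (flagged, never silently
#' zeroed). The un-scaled ratio (no `N` factor) is available with
#' `scale_n = FALSE`.
#'
#' The reserved no-reason/noise topic `"0"` is excluded by default.
#'
#' @param q Topic-weight matrix or a `topic_model` object.
#' @param y Subgroup indicator from [stratify()].
#' @param include_noise Keep the `"0"` topic column.
#' @param scale_n Multiply by `N` (default) so the independence null is 0 on
#'   the log scale.
#' @return A list of class `enrichment`: `theta_log` (topics x subgroups),
#'   `theta`, `n_notes`, plus a long-format data frame `table`.
#' @export
enrichment_scores <- function(q, y, include_noise = FALSE, scale_n = TRUE) {
  if (inherits(q, "topic_model")) q <- q$q
  if (nrow(q) != nrow(y)) stop("q and y must cover the same notes")
  if (any(abs(rowSums(q) - 1) > 1e-6)) {
    stop("rows of q must sum to 1")
  }
  if (!include_noise && "0" %in% colnames(q)) {
    # drop no-reason notes entirely, then the reserved column
    keep <- q[, "0"] < 1 - 1e-12
    q <- q[keep, setdiff(colnames(q), "0"), drop = FALSE]
    y <- y[keep, , drop = FALSE]
    rs <- rowSums(q)
    ok <- rs > 0
    q[ok, ] <- q[ok, , drop = FALSE] / rs[ok]
  }
  n <- nrow(q)
  joint <- t(q) %*% y
  denom <- outer(colSums(q), colSums(y))
  theta <- joint / denom
  if (scale_n) theta <- theta * n
  theta[!is.finite(theta)] <- NA_real_
  theta_log <- suppressWarnings(log(theta))
  theta_log[is.nan(theta_log)] <- NA_real_
  tab <- data.frame(
    topic = rep(rownames(theta), times = ncol(theta)),
    subgroup = rep(colnames(theta), each = nrow(theta)),
    theta = as.vector(theta), log_theta = as.vector(theta_log),
    stringsAsFactors = FALSE)
  structure(list(theta_log = theta_log, theta = theta, n_notes = n,
                 table = tab, scale_n = scale_n),
            class = "enrichment")
}

#' @method print enrichment
#' @export
print.enrichment <- function(x, ...) {
  cat(sprintf("Enrichment over %d topic(s) x %d subgroup(s), n = %d notes\n",
              nrow(x$theta_log), ncol(x$theta_log), x$n_notes))
  print(round(x$theta_log, 3))
  invisible(x)
}

#' Recover planted subgroup enrichments from a synthetic run
#'
#' Validation harness for the enrichment analysis: computes log-theta from a
#' synthetic cohort's planted gold topic labels (one-hot `q`) and its
#' demographics, and returns the cells ranked by log-theta with those above
#' a threshold flagged. With a plan that enriches one (topic, subgroup)
#' cell, that cell should rank first.
#'
#' @param sim A `switch_sim` from [generate_cohort()].
#' @param axis Stratification axis.
#' @param threshold Flag cells with `log_theta >= threshold`.
#' @return Data frame `topic`, `subgroup`, `log_theta`, `detected`, sorted
#'   by decreasing log-theta.
#' @export
recover_planted_enrichment <- function(sim, axis = "race_ethnicity",
                                       threshold = 0.3) {
  stopifnot(inherits(sim, "switch_sim"))
  gold <- sim$gold[!is.na(gold_topic <- sim$gold$true_reason_topic), ,
                   drop = FALSE]
  topics <- sort(unique(gold$true_reason_topic))
  q <- matrix(0, nrow(gold), length(topics),
              dimnames = list(NULL, topics))
  q[cbind(seq_len(nrow(gold)), match(gold$true_reason_topic, topics))] <- 1
  pats <- sim$notes$patient_id[match(gold$note_id, sim$notes$note_id)]
  y <- stratify(pats, sim$demographics, axis)
  enr <- enrichment_scores(q, y)
  tab <- enr$table[order(-enr$table$log_theta, na.last = TRUE), ]
  tab$detected <- !is.na(tab$log_theta) & tab$log_theta >= threshold
  rownames(tab) <- NULL
  tab
}
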