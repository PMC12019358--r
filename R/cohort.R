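#' Apply the cohort attrition filters
#'
#' Reproduces the study-flow attrition over a medication-order table, in a
#' fixed documented order:
#' \enumerate{
#'   \item `non_contraceptive` — therapeutic class is not a contraceptive
#'     class;
#'   \item `excluded_pattern` — non-drug contraceptives (condoms, diaphragms,
#'     spermicides, pH modulators) and emergency contraception;
#'   \item `unmapped` — drug names no modality pattern recognizes (dropped
#'     with a warning, since pattern tables are necessarily incomplete);
#'   \item `missing_start` — orders without a documented start date;
#'   \item `no_followup` — all orders of patients with no encounter at least
#'     `followup_days` after their last (or first, see `followup_anchor`)
#'     remaining contraceptive order;
#'   \item `missing_note` — orders whose encounter has no clinical note;
#'   \item `short_note` — orders whose encounter notes are all at or below
#'     `token_threshold` whitespace tokens;
#'   \item `duplicate` — duplicate (patient, encounter date, modality) rows;
#'     the first is kept.
#' }
#'
#' @param orders Data frame with columns `patient_id`, `encounter_date`,
#'   `start_date`, `drug_name`, `therapeutic_class`.
#' @param notes Data frame with columns `note_id`, `patient_id`,
#'   `encounter_date`, `text`.
#' @param encounters Optional data frame (`patient_id`, `encounter_date`)
#'   of all encounters used for the follow-up criterion; by default the
#'   union of encounter dates seen in `orders` and `notes`.
#' @param patterns Modality pattern table, see [read_pattern_table()].
#' @param followup_days Minimum follow-up window in days ("6 months" is
#'   fixed at 183 days).
#' @param followup_anchor Anchor the follow-up window at the `"last"`
#'   (default) or `"first"` contraceptive order per patient.
#' @param token_threshold Notes with at most this many whitespace tokens are
#'   considered uninformative.
#' @return A list with `orders` (the surviving orders, each with a resolved
#'   `modality` and linked `note_id`) and `attrition`, a data frame of
#'   (filter, removed, remaining records, remaining patients) rows starting
#'   from an `initial` row.
#' @export
apply_filters <- function(orders, notes, encounters = NULL,
                          patterns = read_pattern_table(),
                          followup_days = 183L,
                          followup_anchor = c("last", "first"),
                          token_threshold = 50L) {
  followup_anchor <- match.arg(followup_anchor)
  check_columns(orders, c("patient_id", "encounter_date", "start_date",
                          "drug_name", "therapeutic_class"), "orders")
  check_columns(notes, c("note_id", "patient_id", "encounter_date", "text"),
                "notes")
  if (is.null(encounters)) {
    encounters <- unique(rbind(
      orders[c("patient_id", "encounter_date")],
      notes[c("patient_id", "encounter_date")]))
  }
  check_columns(encounters, c("patient_id", "encounter_date"), "encounters")

  steps <- list()
  note_step <- function(name, keep) {
    steps[[length(steps) + 1L]] <<- data.frame(
      filter = name, removed = sum(!keep), remaining = sum(keep),
      patients = length(unique(orders$patient_id[keep])),
      stringsAsFactors = FALSE)
    orders[keep, , drop = FALSE]
  }
  steps[[1]] <- data.frame(filter = "initial", removed = 0L,
                           remaining = nrow(orders),
                           patients = length(unique(orders$patient_id)),
                           stringsAsFactors = FALSE)

  mapped <- map_to_modality(orders$drug_name, orders$therapeutic_class,
                            patterns = patterns)
  orders$modality <- mapped
  orders <- note_step("non_contraceptive", mapped != "non_contraceptive")
  orders <- note_step("excluded_pattern",
                      orders$modality != "excluded")
  n_unmapped <- sum(orders$modality == "unmapped")
  if (n_unmapped > 0) {
    warning(n_unmapped, " order(s) with unmapped drug names were dropped; ",
            "extend the pattern table to keep them")
  }
  orders <- note_step("unmapped", orders$modality != "unmapped")
  orders <- note_step("missing_start", !is.na(orders$start_date))

  anchor <- tapply(orders$start_date, orders$patient_id,
                   if (followup_anchor == "last") max else min)
  last_enc <- tapply(encounters$encounter_date, encounters$patient_id, max)
  ok_pat <- names(anchor)[
    !is.na(last_enc[names(anchor)]) &
      last_enc[names(anchor)] >= anchor + followup_days]
  orders <- note_step("no_followup", orders$patient_id %in% ok_pat)

  informative <- notes[count_tokens(notes$text) > token_threshold, ,
                       drop = FALSE]
  any_note_key <- unique(paste(notes$patient_id, notes$encounter_date))
  good_note_key <- unique(paste(informative$patient_id,
                                informative$encounter_date))
  okey <- paste(orders$patient_id, orders$encounter_date)
  orders <- note_step("missing_note", okey %in% any_note_key)
  okey <- paste(orders$patient_id, orders$encounter_date)
  orders <- note_step("short_note", okey %in% good_note_key)

  dkey <- paste(orders$patient_id, orders$encounter_date, orders$modality)
  orders <- note_step("duplicate", !duplicated(dkey))

  # link each order to the longest informative note at its encounter
  informative$nchar <- nchar(informative$text)
  informative <- informative[order(informative$patient_id,
                                   informative$encounter_date,
                                   -informative$nchar), ]
  best <- informative[!duplicated(paste(informative$patient_id,
                                        informative$encounter_date)), ]
  orders$note_id <- best$note_id[match(
    paste(orders$patient_id, orders$encounter_date),
    paste(best$patient_id, best$encounter_date))]

  rownames(orders) <- NULL
  list(orders = orders, attrition = do.call(rbind, steps))
}

#' Detect contraceptive switches
#'
#' A switch is a difference in the set of prescribed modalities between a
#' patient's consecutive encounters, with encounters ordered by documented
#' start date. `stopped` is the set difference previous minus current,
#' `started` current minus previous; consecutive encounters with equal
#' modality sets emit nothing.
#'
#' @param orders Filtered order table from [apply_filters()] (columns
#'   `patient_id`, `encounter_date`, `start_date`, `modality`, and optionally
#'   `note_id`).
#' @param check_sorted If `TRUE`, error when any patient's orders are not in
#'   non-decreasing start-date order instead of sorting silently.
#' @return Data frame of switch events: `patient_id`,
#'   `prev_encounter_date`, `new_encounter_date`, `stopped`, `started`
#'   (each a `;`-joined modality set, sorted alphabetically), `note_id` (the
#'   note linked to the new encounter, if present).
#' @export
detect_switches <- function(orders, check_sorted = FALSE) {
  check_columns(orders, c("patient_id", "encounter_date", "start_date",
                          "modality"), "orders")
  if (!nrow(orders)) {
    return(data.frame(patient_id = character(0),
                      prev_encounter_date = integer(0),
                      new_encounter_date = integer(0),
                      stopped = character(0), started = character(0),
                      note_id = character(0), stringsAsFactors = FALSE))
  }
  if (check_sorted) {
    bad <- tapply(orders$start_date, orders$patient_id,
                  function(d) is.unsorted(d, na.rm = TRUE))
    if (any(unlist(bad))) stop("orders must be sorted by start date per patient")
  }
  if (is.null(orders$note_id)) orders$note_id <- NA_character_
  # stable deterministic ordering: start date, then modality name
  orders <- orders[order(orders$patient_id, orders$start_date,
                         orders$modality, method = "radix"), ]
  events <- lapply(split(orders, orders$patient_id), function(df) {
    encs <- unique(df$encounter_date[order(df$start_date)])
    if (length(encs) < 2L) return(NULL)
    sets <- lapply(encs, function(e)
      sort(unique(df$modality[df$encounter_date == e])))
    out <- vector("list", length(encs) - 1L)
    for (j in seq_len(length(encs) - 1L)) {
      prev <- sets[[j]]; cur <- sets[[j + 1L]]
      if (!setequal(prev, cur)) {
        nid <- df$note_id[df$encounter_date == encs[j + 1L]][1L]
        out[[j]] <- data.frame(
          patient_id = df$patient_id[1L],
          prev_encounter_date = encs[j], new_encounter_date = encs[j + 1L],
          stopped = paste(sort(setdiff(prev, cur)), collapse = ";"),
          started = paste(sort(setdiff(cur, prev)), collapse = ";"),
          note_id = nid, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, events)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0),
                      prev_encounter_date = integer(0),
                      new_encounter_date = integer(0),
                      stopped = character(0), started = character(0),
                      note_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Modality-by-modality switch matrix
#'
#' Tabulates single-modality switch events into a stopped-by-started count
#' matrix over the six modalities. Events whose stopped or started field
#' holds more than one modality contribute one count per (stopped, started)
#' pair.
#'
#' @param switches Data frame from [detect_switches()].
#' @return A 6 x 6 integer matrix (rows: stopped, columns: started).
#' @export
switch_matrix <- function(switches) {
  mods <- modality_levels()
  m <- matrix(0L, 6, 6, dimnames = list(stopped = mods, started = mods))
  for (i in seq_len(nrow(switches))) {
    for (s in strsplit(switches$stopped[i], ";")[[1]]) {
      for (t in strsplit(switches$started[i], ";")[[1]]) {
        if (s %in% mods && t %in% mods) m[s, t] <- m[s, t] + 1L
      }
    }
  }
  m
}

#' Compare demographics between switch and non-switch cohorts
#'
#' Builds a Table-1-style comparison: mean (SD) and a two-sided t-test for
#' continuous variables; counts and percentages among non-missing values
#' with a chi-square test (no continuity correction, i.e. the textbook
#' \eqn{\sum (O-E)^2/E} statistic) for categorical variables. A categorical
#' variable with a single observed level in both groups is marked
#' not-applicable rather than tested.
#'
#' @param switch_dem,nonswitch_dem Demographics data frames for the two
#'   cohorts.
#' @param continuous,categorical Column names to compare.
#' @return A list with one entry per variable; continuous entries carry
#'   `mean`, `sd`, `statistic`, `p_value`, categorical entries a count/percent
#'   table plus `statistic`, `df`, `p_value` (or `applicable = FALSE`).
#' @export
demographic_comparison <- function(switch_dem, nonswitch_dem,
                                   continuous = "age_first_rx",
                                   categorical = c("race_ethnicity",
                                                   "preferred_language")) {
  if (!nrow(switch_dem) || !nrow(nonswitch_dem)) {
    stop("both cohorts must be non-empty")
  }
  out <- list()
  for (v in continuous) {
    a <- switch_dem[[v]]; b <- nonswitch_dem[[v]]
    tt <- stats::t.test(a, b, alternative = "two.sided")
    out[[v]] <- list(
      type = "continuous",
      switch = c(mean = mean(a, na.rm = TRUE), sd = stats::sd(a, na.rm = TRUE),
                 n = sum(!is.na(a))),
      nonswitch = c(mean = mean(b, na.rm = TRUE),
                    sd = stats::sd(b, na.rm = TRUE), n = sum(!is.na(b))),
      statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  for (v in categorical) {
    a <- switch_dem[[v]]; b <- nonswitch_dem[[v]]
    lev <- sort(unique(c(a[!is.na(a)], b[!is.na(b)])))
    counts <- rbind(switch = table(factor(a, levels = lev)),
                    nonswitch = table(factor(b, levels = lev)))
    pct <- sweep(counts, 1, rowSums(counts), "/") * 100
    entry <- list(type = "categorical", levels = lev, counts = counts,
                  percent = pct,
                  missing = c(switch = sum(is.na(a)),
                              nonswitch = sum(is.na(b))))
    usable <- counts[, colSums(counts) > 0, drop = FALSE]
    if (ncol(usable) < 2L) {
      entry$applicable <- FALSE
    } else {
      cs <- suppressWarnings(stats::chisq.test(usable, correct = FALSE))
      entry$applicable <- TRUE
      entry$statistic <- unname(cs$statistic)
      entry$df <- unname(cs$parameter)
      entry$p_value <- cs$p.value
    }
    out[[v]] <- entry
  }
  out
}
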