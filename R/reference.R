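#' Reference cohort summary counts
#'
#' Published summary counts from the original observational study of
#' contraceptive switching in a large academic medical center EHR (the
#' analysis this package generalizes). They are inputs for worked-example
#' arithmetic — recomputing the demographic percentages and switch-rate
#' fractions from the printed counts — not outputs of this package.
#'
#' @return A list with `n_switch`, `n_nonswitch`, `age` (mean/sd per group),
#'   `race_ethnicity`, `preferred_language` and `first_modality` count
#'   tables (with per-group missing counts), and `switches` (total events,
#'   most/least common modality pairs).
#' @export
reference_cohort_counts <- function() {
  list(
    n_cohort_patients = 20274L,
    n_switch = 1515L,
    n_nonswitch = 15907L,
    age = list(switch = c(mean = 25.9, sd = 7.7),
               nonswitch = c(mean = 29.1, sd = 8.4)),
    race_ethnicity = list(
      missing = c(switch = 32L, nonswitch = 815L),
      counts = data.frame(
        category = c("White", "Latinx", "Black or African American",
                     "Asian", "Other", "Multi-Race/Ethnicity"),
        switch = c(490L, 286L, 286L, 237L, 115L, 69L),
        nonswitch = c(6813L, 2281L, 1237L, 3071L, 1224L, 466L),
        printed_pct_switch = c(33.0, 19.3, 19.3, 16.0, 7.8, 4.7),
        printed_pct_nonswitch = c(45.1, 15.1, 8.2, 20.3, 8.1, 3.1),
        stringsAsFactors = FALSE)),
    preferred_language = list(
      missing = c(switch = 0L, nonswitch = 5L),
      counts = data.frame(
        category = c("English", "Spanish", "Other"),
        switch = c(1474L, 14L, 27L),
        nonswitch = c(15405L, 281L, 216L),
        printed_pct_switch = c(97.3, 0.9, 1.8),
        stringsAsFactors = FALSE)),
    first_modality = data.frame(
      category = c("Implant", "Injectable", "Intrauterine", "Intravaginal",
                   "Oral", "Transdermal"),
      switch = c(160L, 199L, 64L, 244L, 661L, 187L),
      nonswitch = c(799L, 853L, 1266L, 1935L, 10496L, 558L),
      printed_pct_switch = c(10.6, 13.1, 4.2, 16.1, 43.6, 12.3),
      stringsAsFactors = FALSE),
    switches = list(
      n_events = 1964L,
      most_common = list(stopped = "Oral", started = "Intravaginal",
                         n = 205L, printed_pct = 10.5),
      least_common = list(stopped = "IUD", started = "Injectable",
                          n = 6L, printed_pct = 0.31)))
}

#' Percentages among non-missing from category counts
#'
#' Recomputes the percentage column of a demographic count table the way
#' summary tables report it: each category count divided by the sum of
#' non-missing counts, times 100.
#'
#' @param counts Integer vector of category counts.
#' @return Numeric vector of percentages summing to 100.
#' @export
category_percentages <- function(counts) {
  100 * counts / sum(counts)
}
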