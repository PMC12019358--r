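#' Contraceptive modality levels
#'
#' The closed set of six delivery classes every drug product is mapped to:
#' Oral, Implant, IUD (intrauterine device), Injectable (intramuscular or
#' subcutaneous), Transdermal and Intravaginal.
#'
#' @return Character vector of the six modality names, in presentation order.
#' @export
modality_levels <- function() {
  c("Oral", "Implant", "IUD", "Injectable", "Transdermal", "Intravaginal")
}

#' Read a modality pattern table
#'
#' Loads the YAML pattern table that maps free-text drug names to
#' contraceptive modalities. The table has two blocks: `exclude` (regex
#' patterns for non-drug contraceptives and emergency contraception, tested
#' first) and `modalities` (a named list of regex vectors, tested in listed
#' order; first match wins). All matching is case-insensitive.
#'
#' @param path Path to a YAML file; defaults to the table shipped with the
#'   package.
#' @return A list with elements `exclude` (character) and `modalities`
#'   (named list of character vectors).
#' @export
read_pattern_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "modality_patterns.yaml",
                        package = "switchscope", mustWork = TRUE)
  }
  tab <- yaml::read_yaml(path)
  if (!is.list(tab) || !all(c("exclude", "modalities") %in% names(tab))) {
    stop("pattern table must contain 'exclude' and 'modalities' blocks")
  }
  unknown <- setdiff(names(tab$modalities), modality_levels())
  if (length(unknown)) {
    stop("pattern table names unknown modalities: ",
         paste(unknown, collapse = ", "))
  }
  tab$exclude <- as.character(unlist(tab$exclude))
  tab$modalities <- lapply(tab$modalities, function(x) as.character(unlist(x)))
  tab
}

#' Map drug names to contraceptive modalities
#'
#' Applies the pattern table to a vector of drug names. Orders whose
#' therapeutic class does not look like a contraceptive class are labelled
#' `"non_contraceptive"`; names hitting an exclusion pattern (emergency
#' contraception, condoms, diaphragms, spermicides, pH modulators) are
#' labelled `"excluded"`; names matching no pattern are `"unmapped"`.
#'
#' @param drug_name Character vector of drug descriptions; must be non-empty
#'   strings.
#' @param therapeutic_class Optional character vector (recycled) of
#'   therapeutic-class labels; when supplied, rows whose class does not match
#'   `class_pattern` are returned as `"non_contraceptive"` without consulting
#'   the drug name.
#' @param patterns A pattern table from [read_pattern_table()].
#' @param class_pattern Case-insensitive regex identifying contraceptive
#'   therapeutic classes.
#' @return Character vector with values in
#'   `c(modality_levels(), "excluded", "unmapped", "non_contraceptive")`.
#' @examples
#' map_to_modality("norethindrone 0.35 mg oral tablet")
#' map_to_modality("levonorgestrel 1.5 mg tablet (emergency)")
#' @export
map_to_modality <- function(drug_name, therapeutic_class = NULL,
                            patterns = read_pattern_table(),
                            class_pattern = "contracept") {
  if (length(drug_name) == 0L) return(character(0))
  if (any(is.na(drug_name) | !nzchar(trimws(drug_name)))) {
    stop("drug_name must be non-empty")
  }
  out <- rep("unmapped", length(drug_name))
  consider <- rep(TRUE, length(drug_name))
  if (!is.null(therapeutic_class)) {
    therapeutic_class <- rep_len(as.character(therapeutic_class),
                                 length(drug_name))
    noncon <- !grepl(class_pattern, therapeutic_class, ignore.case = TRUE)
    noncon[is.na(noncon)] <- TRUE
    out[noncon] <- "non_contraceptive"
    consider <- !noncon
  }
  hit_any <- function(pats, x) {
    hits <- rep(FALSE, length(x))
    for (p in pats) hits <- hits | grepl(p, x, ignore.case = TRUE, perl = TRUE)
    hits
  }
  excl <- consider & hit_any(patterns$exclude, drug_name)
  out[excl] <- "excluded"
  consider <- consider & !excl
  for (mod in names(patterns$modalities)) {
    hit <- consider & hit_any(patterns$modalities[[mod]], drug_name)
    out[hit] <- mod
    consider <- consider & !hit
  }
  out
}

#' Normalize extracted drug text to a modality
#'
#' Maps a free-text drug mention produced by a note extractor onto the six
#' modalities using the same pattern table as the cohort pipeline.
#' Exclusion hits, unmatched text, empty strings and redaction placeholders
#' normalize to `NA` (no modality).
#'
#' @param text Character vector of extracted drug mentions.
#' @inheritParams map_to_modality
#' @return Character vector of modality names or `NA_character_`.
#' @export
normalize_to_modality <- function(text, patterns = read_pattern_table()) {
  out <- rep(NA_character_, length(text))
  ok <- !is.na(text) & nzchar(trimws(text)) &
    !grepl("\\[REDACTED\\]", text, fixed = FALSE)
  if (any(ok)) {
    mapped <- map_to_modality(text[ok], patterns = patterns)
    mapped[!mapped %in% modality_levels()] <- NA_character_
    out[ok] <- mapped
  }
  out
}
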