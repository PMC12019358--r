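#' Extract switching information from a clinical note
#'
#' The pluggable extraction seam: any extractor maps note text to an
#' `(stopped, started, reason)` triple. This reference implementation is a
#' deterministic cue-phrase rule set:
#' \itemize{
#'   \item stopped — in each sentence containing a stop cue (`stopped`,
#'     `discontinu`, `removal of`, `came off`), the first drug/modality
#'     mention after the cue, normalized via the pattern table;
#'   \item started — likewise for start cues (`started`, `starting`,
#'     `switching to`, `begin`, `placed`); when several sentences carry a
#'     start cue the last mention wins (plans are typically stated at the
#'     end of a note);
#'   \item reason — the clause following a causal cue (`because`, `due to`,
#'     `reports`) up to the end of the sentence; `NA` when no causal cue is
#'     present.
#' }
#' Redaction placeholders (`[REDACTED]`) normalize to no modality, mirroring
#' the failure mode deidentified notes exhibit for person-name-like brand
#' names.
#'
#' @param text Character vector of note texts (non-empty).
#' @param note_id Optional identifiers carried into the result.
#' @param patterns Modality pattern table.
#' @return Data frame with columns `note_id`, `stopped`, `started`
#'   (modality or `NA`), `reason` (text or `NA`) and `raw_output`.
#' @examples
#' extract_switch_info(
#'   "Pt stopped norethindrone pills due to spotting; starting NuvaRing.")
#' @export
extract_switch_info <- function(text, note_id = NULL,
                                patterns = read_pattern_table()) {
  if (!length(text) || any(is.na(text) | !nzchar(text))) {
    stop("note text must be non-empty")
  }
  if (is.null(note_id)) note_id <- sprintf("note%04d", seq_along(text))
  stop_cues <- c("stopped", "discontinu\\w*", "removal of", "came off")
  start_cues <- c("started", "starting", "switching to", "begin\\w*",
                  "placed")
  reason_cues <- c("because", "due to", "reports")

  one <- function(txt, id) {
    sentences <- strsplit(txt, "(?<=[.;])\\s+", perl = TRUE)[[1]]
    find_after_cue <- function(cues, take_last = FALSE) {
      hits <- character(0)
      for (s in sentences) {
        for (cue in cues) {
          m <- regexpr(cue, s, ignore.case = TRUE, perl = TRUE)
          if (m > 0) {
            tail_txt <- substring(s, m + attr(m, "match.length"))
            mod <- first_mention(tail_txt)
            if (!is.na(mod)) hits <- c(hits, mod)
            break
          }
        }
      }
      if (!length(hits)) NA_character_
      else if (take_last) hits[length(hits)] else hits[1L]
    }
    first_mention <- function(s) {
      # a redacted mention cannot be recovered: the drug slot holds only the
      # deidentification placeholder
      if (grepl("\\[REDACTED\\]", s)) return(NA_character_)
      words <- strsplit(trimws(s), "\\s+")[[1]]
      if (!length(words)) return(NA_character_)
      # scan growing word windows so multi-word mentions resolve at their
      # earliest position
      for (i in seq_along(words)) {
        for (j in i:min(i + 3L, length(words))) {
          cand <- paste(words[i:j], collapse = " ")
          mod <- normalize_to_modality(cand, patterns = patterns)
          if (!is.na(mod)) return(mod)
        }
      }
      NA_character_
    }
    reason <- NA_character_
    for (s in sentences) {
      for (cue in reason_cues) {
        m <- regexpr(paste0("\\b", cue, "\\b"), s, ignore.case = TRUE,
                     perl = TRUE)
        if (m > 0) {
          clause <- substring(s, m + attr(m, "match.length"))
          clause <- sub("[.;]\\s*$", "", trimws(clause))
          if (nzchar(clause)) reason <- clause
          break
        }
      }
      if (!is.na(reason)) break
    }
    data.frame(note_id = id,
               stopped = find_after_cue(stop_cues),
               started = find_after_cue(start_cues, take_last = TRUE),
               reason = reason, raw_output = txt, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(one, text, note_id))
  rownames(out) <- NULL
  out
}

#' Derive silver-standard labels from structured orders
#'
#' Weak started/stopped labels taken from the structured order record rather
#' than human annotation: for every detected switch event, `stopped` and
#' `started` are the event's set differences. When a set holds more than one
#' modality the alphabetically first is used (documented tie-break). Notes
#' at non-switch encounters yield no label.
#'
#' @param switches Data frame from [detect_switches()]; events lacking a
#'   linked note are skipped.
#' @return Data frame `note_id`, `stopped`, `started`.
#' @export
derive_silver_labels <- function(switches) {
  check_columns(switches, c("note_id", "stopped", "started"), "switches")
  sw <- switches[!is.na(switches$note_id), , drop = FALSE]
  first_of <- function(x) {
    vapply(strsplit(x, ";"), function(v) sort(v)[1L], character(1))
  }
  out <- data.frame(note_id = sw$note_id,
                    stopped = first_of(sw$stopped),
                    started = first_of(sw$started), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
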