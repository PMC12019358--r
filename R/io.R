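#' Read and write pipeline tables
#'
#' The pipeline exchanges plain-text formats: orders/demographics/labels as
#' CSV and clinical notes as JSONL with one `{note_id, patient_id,
#' encounter_date, text}` object per line.
#'
#' @param path File path.
#' @return `read_notes_jsonl()` returns a data frame with columns `note_id`,
#'   `patient_id`, `encounter_date`, `text`.
#' @export
read_notes_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(note_id = as.character(x$note_id),
               patient_id = as.character(x$patient_id),
               encounter_date = as.integer(x$encounter_date),
               text = as.character(x$text), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname read_notes_jsonl
#' @param notes Data frame of notes to serialize.
#' @export
write_notes_jsonl <- function(notes, path) {
  stopifnot(all(c("note_id", "patient_id", "encounter_date", "text")
                %in% names(notes)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    writeLines(jsonlite::toJSON(list(
      note_id = notes$note_id[i], patient_id = notes$patient_id[i],
      encounter_date = notes$encounter_date[i], text = notes$text[i]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

count_tokens <- function(text) {
  lengths(strsplit(trimws(text), "\\s+"))
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(df)
}
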