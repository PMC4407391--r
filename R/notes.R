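#' Store a note in the database
#'
#' Table timestamps record *when* data changed; notes record *what* and
#' *why*.  A note holds free-text comments and an arbitrary text payload —
#' typically the log file of a committing run — plus keywords for
#' retrieval, so the data-cleaning record becomes a permanent part of the
#' database.
#'
#' @param db a `gdb` object.
#' @param keywords character vector of keywords.
#' @param comment short free-text comment.
#' @param payload text payload (e.g. the lines of a log file, collapsed
#'   with newlines if given as a vector).
#' @return The note id.
#' @export
store_note <- function(db, keywords, comment = "", payload = "") {
  if (length(payload) > 1L) payload <- paste(payload, collapse = "\n")
  gv_insert(db, "notes", data.frame(
    keywords = paste(keywords, collapse = ","),
    comment = comment, payload = payload, stringsAsFactors = FALSE))
}

#' Retrieve notes by keyword
#'
#' @param db a `gdb` object.
#' @param keyword a single keyword; every note tagged with it (among
#'   possibly several) is returned.
#' @return The matching rows of the notes table (possibly empty).
#' @export
find_notes <- function(db, keyword) {
  nt <- db$tables$notes
  hit <- vapply(strsplit(nt$keywords, ",", fixed = TRUE),
                function(k) keyword %in% k, logical(1))
  nt[hit, , drop = FALSE]
}
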