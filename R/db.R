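# Relational schema: one entry per table; `key` columns form the natural key
# used by the load protocol, `payload` columns are the compared/updated part,
# `id` (if any) is an opaque integer assigned on insert.
.gv_schema <- list(
  members = list(
    cols = c(member_id = "int", pedigree = "chr", person = "chr",
             father = "chr", mother = "chr", sex = "chr", created = "chr"),
    key = c("pedigree", "person"), id = "member_id",
    payload = c("father", "mother", "sex")),
  member_aliases = list(
    cols = c(alias_pedigree = "chr", alias_person = "chr",
             member_id = "int", created = "chr"),
    key = c("alias_pedigree", "alias_person"), id = NULL,
    payload = "member_id"),
  samples = list(
    cols = c(sample_id = "int", sample_name = "chr", member_id = "int",
             plate = "chr", well = "chr", preferred = "lgl",
             created = "chr"),
    key = "sample_name", id = "sample_id",
    payload = c("member_id", "plate", "well", "preferred")),
  traitmeta = list(
    cols = c(trait_id = "int", name = "chr", kind = "chr", created = "chr"),
    key = "name", id = "trait_id", payload = "kind"),
  traits = list(
    cols = c(member_id = "int", trait_id = "int", value = "chr",
             created = "chr"),
    key = c("member_id", "trait_id"), id = NULL, payload = "value"),
  markers = list(
    cols = c(marker_id = "int", name = "chr", created = "chr"),
    key = "name", id = "marker_id", payload = character()),
  marker_aliases = list(
    cols = c(alias_name = "chr", marker_id = "int", created = "chr"),
    key = "alias_name", id = NULL, payload = "marker_id"),
  marker_info = list(
    cols = c(marker_id = "int", build = "chr", chromosome = "int",
             bp = "num", avg_cm = "num", female_cm = "num",
             male_cm = "num", created = "chr"),
    key = c("marker_id", "build"), id = NULL,
    payload = c("chromosome", "bp", "avg_cm", "female_cm", "male_cm")),
  technologies = list(
    cols = c(technology_id = "int", name = "chr", created = "chr"),
    key = "name", id = "technology_id", payload = character()),
  experiments = list(
    cols = c(experiment_id = "int", name = "chr", date = "chr",
             technology_id = "int", trust = "int", created = "chr"),
    key = "name", id = "experiment_id",
    payload = c("date", "technology_id", "trust")),
  allele_map = list(
    cols = c(experiment_id = "int", marker_id = "int", from_allele = "chr",
             to_allele = "chr", created = "chr"),
    key = c("experiment_id", "marker_id", "from_allele"), id = NULL,
    payload = "to_allele"),
  genotypes = list(
    cols = c(geno_id = "int", member_id = "int", marker_id = "int",
             experiment_id = "int", technology_id = "int",
             sample_id = "int", allele1 = "chr", allele2 = "chr",
             active = "lgl", created = "chr"),
    key = NULL, id = "geno_id", payload = character()),
  layouts = list(
    cols = c(layout = "chr", block_size = "int", created = "chr"),
    key = "layout", id = NULL, payload = "block_size"),
  snpblocks = list(
    cols = c(layout = "chr", marker_id = "int", chromosome = "int",
             block_index = "int", offset = "int", created = "chr"),
    key = c("layout", "marker_id"), id = NULL,
    payload = c("chromosome", "block_index", "offset")),
  genotypeblocks = list(
    cols = c(sample_id = "int", experiment_id = "int", layout = "chr",
             chromosome = "int", block_index = "int", payload = "chr",
             created = "chr"),
    key = c("sample_id", "experiment_id", "layout", "chromosome",
            "block_index"),
    id = NULL, payload = "payload"),
  notes = list(
    cols = c(note_id = "int", keywords = "chr", comment = "chr",
             payload = "chr", created = "chr"),
    key = NULL, id = "note_id", payload = character())
)

gv_empty_table <- function(table) {
  cols <- .gv_schema[[table]]$cols
  proto <- list(int = integer(0), num = numeric(0), chr = character(0),
                lgl = logical(0))
  out <- lapply(unname(cols), function(t) proto[[t]])
  names(out) <- names(cols)
  as.data.frame(out, stringsAsFactors = FALSE)
}

gv_timestamp <- function() format(Sys.time(), "%Y-%m-%d %H:%M:%S")

#' Create an empty genotype database
#'
#' Builds the full relational schema in memory: pedigree members and their
#' aliases, samples, traits, markers with aliases and per-build map
#' information, technologies and experiments, allele relabelling maps, the
#' row-per-genotype table for targeted experiments, the block-packed
#' genotype table with its marker-location index for genome-wide
#' experiments, and a notes table.  The object is an environment, so the
#' loading and import functions mutate it in place; transactional rollback
#' is provided by [gdb_snapshot()]/[gdb_restore()] and is applied
#' automatically by every committing operation.
#'
#' @param path optional directory used by [gdb_save()] as the default
#'   on-disk location.
#' @return An object of class `gdb`.
#' @seealso [gdb_load()], [gdb_save()], [gdb_open()]
#' @export
gdb_create <- function(path = NULL) {
  db <- new.env(parent = emptyenv())
  db$tables <- lapply(stats::setNames(names(.gv_schema), names(.gv_schema)),
                      gv_empty_table)
  db$ids <- stats::setNames(
    rep(0L, length(.gv_schema)), names(.gv_schema))
  db$path <- path
  db$log <- character(0)
  class(db) <- "gdb"
  db
}

#' @export
print.gdb <- function(x, ...) {
  cat("<genovault database>\n")
  n <- vapply(x$tables, nrow, integer(1))
  n <- n[n > 0]
  if (!length(n)) {
    cat("  (empty)\n")
  } else {
    for (t in names(n)) cat(sprintf("  %-16s %d row(s)\n", t, n[[t]]))
  }
  invisible(x)
}

#' Access the raw tables of a database
#'
#' @param db a `gdb` object.
#' @param table optional table name; if omitted, the full named list of
#'   data frames is returned.
#' @return A data frame, or a named list of data frames.
#' @export
gdb_tables <- function(db, table = NULL) {
  if (is.null(table)) return(db$tables)
  if (!table %in% names(db$tables)) stop("no such table: ", table)
  db$tables[[table]]
}

#' Snapshot and restore the database state
#'
#' Every committing operation takes a snapshot before touching the store and
#' restores it if any error occurs, so a failed run never leaves partial
#' data behind.  The snapshot is a plain list value; R's copy-on-modify
#' semantics make it an immutable image of the store.
#'
#' @param db a `gdb` object.
#' @param snapshot a value previously returned by `gdb_snapshot()`.
#' @return `gdb_snapshot()` returns the snapshot; `gdb_restore()` returns
#'   the database, invisibly.
#' @export
gdb_snapshot <- function(db) {
  list(tables = db$tables, ids = db$ids)
}

#' @rdname gdb_snapshot
#' @export
gdb_restore <- function(db, snapshot) {
  db$tables <- snapshot$tables
  db$ids <- snapshot$ids
  invisible(db)
}

# Insert rows (a data frame with a subset of schema columns); assigns ids and
# timestamps.  Returns the assigned ids (or row count for id-less tables).
gv_insert <- function(db, table, rows) {
  spec <- .gv_schema[[table]]
  n <- nrow(rows)
  if (n == 0L) return(integer(0))
  full <- gv_empty_table(table)
  out <- as.list(full)
  types <- spec$cols
  for (col in names(types)) {
    if (col %in% names(rows)) {
      v <- rows[[col]]
      out[[col]] <- switch(types[[col]],
        int = as.integer(v), num = as.numeric(v),
        chr = as.character(v), lgl = as.logical(v))
    } else {
      out[[col]] <- rep(switch(types[[col]], int = NA_integer_,
                               num = NA_real_, chr = NA_character_,
                               lgl = NA), n)
    }
  }
  ids <- integer(0)
  if (!is.null(spec$id)) {
    have <- out[[spec$id]]
    if (all(is.na(have))) {
      ids <- db$ids[[table]] + seq_len(n)
      db$ids[[table]] <- db$ids[[table]] + n
      out[[spec$id]] <- ids
    } else {
      ids <- as.integer(have)
      db$ids[[table]] <- max(db$ids[[table]], ids)
    }
  }
  if (all(is.na(out$created))) out$created <- rep(gv_timestamp(), n)
  new <- as.data.frame(out, stringsAsFactors = FALSE)
  db$tables[[table]] <- rbind(db$tables[[table]], new)
  if (length(ids)) ids else n
}

# Remove rows by logical mask.
gv_delete_rows <- function(db, table, mask) {
  db$tables[[table]] <- db$tables[[table]][!mask, , drop = FALSE]
  sum(mask)
}

#' Save and reopen a database as a directory of delimited text files
#'
#' Each table is written as one tab-separated file plus a small metadata
#' file holding the id counters.  Text fields containing delimiters are
#' quoted, so note payloads (e.g. stored log files) survive the round trip.
#'
#' @param db a `gdb` object.
#' @param path directory to write to / read from.
#' @return `gdb_save()` returns the path invisibly; `gdb_open()` returns a
#'   `gdb` object.
#' @export
gdb_save <- function(db, path = db$path) {
  if (is.null(path)) stop("no path given and the database has none recorded")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (t in names(db$tables)) {
    data.table::fwrite(db$tables[[t]], file.path(path, paste0(t, ".tsv")),
                       sep = "\t", quote = TRUE, na = "NA")
  }
  writeLines(paste(names(db$ids), db$ids, sep = "\t"),
             file.path(path, "_ids.tsv"))
  db$path <- path
  invisible(path)
}

#' @rdname gdb_save
#' @export
gdb_open <- function(path) {
  if (!dir.exists(path)) stop("no database directory at ", path)
  db <- gdb_create(path)
  cls <- c(int = "integer", num = "numeric", chr = "character",
           lgl = "logical")
  for (t in names(.gv_schema)) {
    f <- file.path(path, paste0(t, ".tsv"))
    if (!file.exists(f)) next
    types <- .gv_schema[[t]]$cols
    d <- data.table::fread(f, sep = "\t", header = TRUE,
                           colClasses = unname(cls[types]),
                           na.strings = "NA", data.table = FALSE)
    if (nrow(d)) db$tables[[t]] <- d[, names(types), drop = FALSE]
  }
  idf <- file.path(path, "_ids.tsv")
  if (file.exists(idf)) {
    lines <- strsplit(readLines(idf), "\t", fixed = TRUE)
    for (ln in lines) db$ids[[ln[[1]]]] <- as.integer(ln[[2]])
  }
  db
}
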