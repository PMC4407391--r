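# Which tables hold foreign keys into which id column; consulted before a
# replace/delete removes rows that other tables still reference.
.gv_references <- list(
  members = list(c("member_aliases", "member_id"), c("samples", "member_id"),
                 c("traits", "member_id"), c("genotypes", "member_id")),
  markers = list(c("marker_aliases", "marker_id"),
                 c("marker_info", "marker_id"),
                 c("allele_map", "marker_id"), c("genotypes", "marker_id"),
                 c("snpblocks", "marker_id")),
  samples = list(c("genotypes", "sample_id"),
                 c("genotypeblocks", "sample_id")),
  traitmeta = list(c("traits", "trait_id")),
  technologies = list(c("experiments", "technology_id"),
                      c("genotypes", "technology_id")),
  experiments = list(c("genotypes", "experiment_id"),
                     c("allele_map", "experiment_id"),
                     c("genotypeblocks", "experiment_id"))
)

gv_check_unreferenced <- function(db, table, ids) {
  refs <- .gv_references[[table]]
  if (is.null(refs) || !length(ids)) return(invisible(TRUE))
  for (r in refs) {
    hit <- db$tables[[r[[1]]]][[r[[2]]]] %in% ids
    if (any(hit)) {
      stop("cannot remove ", table, " row(s) still referenced by ",
           r[[1]], " (", sum(hit), " reference(s)); use update instead")
    }
  }
  invisible(TRUE)
}

gv_load_modes <- c("dry_run", "commit", "commit_replace", "commit_update",
                   "compare", "delete")

new_load_report <- function() {
  structure(list(n_parsed = 0L, n_new = 0L, n_changed = 0L, n_deleted = 0L,
                 errors = character(0), warnings = character(0),
                 committed = FALSE),
            class = "load_report")
}

#' @export
print.load_report <- function(x, ...) {
  cat(sprintf("<load report> parsed %d | new %d | changed %d | deleted %d | %s\n",
              x$n_parsed, x$n_new, x$n_changed, x$n_deleted,
              if (x$committed) "committed" else "not committed"))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  for (e in x$errors) cat("  error: ", e, "\n", sep = "")
  invisible(x)
}

gv_key_string <- function(df, key) {
  do.call(paste, c(unname(df[key]), list(sep = "\r")))
}

gv_row_differs <- function(a, b, cols) {
  if (!length(cols)) return(rep(FALSE, nrow(a)))
  diff <- rep(FALSE, nrow(a))
  for (col in cols) {
    x <- a[[col]]; y <- b[[col]]
    same <- (is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y)
    diff <- diff | !same
  }
  diff
}

#' Load validated records into a table under the commit-flag protocol
#'
#' All flat-file loading follows the same protocol.  Without a committing
#' mode nothing is written: `dry_run` parses and validates only, `compare`
#' additionally reports every record whose stored payload differs from the
#' file.  `commit` inserts only records whose natural key is absent from the
#' store; records whose key exists but whose payload differs produce a
#' warning and are left untouched, so committing the same file twice is a
#' no-op and committing an extended file adds just the new rows.
#' `commit_replace` deletes-then-reinserts changed records (refused when the
#' old row is referenced from other tables), `commit_update` modifies them
#' in place (keeping their id), and `delete` removes every listed record.
#' Any error during a committing mode rolls the store back to its pre-run
#' state.
#'
#' @param db a `gdb` object.
#' @param table table name (see the package schema).
#' @param records a data frame of input records; entity-specific columns are
#'   validated and resolved (e.g. parent names, marker names) before the
#'   diff against the store.
#' @param mode one of `"dry_run"`, `"commit"`, `"commit_replace"`,
#'   `"commit_update"`, `"compare"`, `"delete"`.
#' @return A `load_report` with counts of parsed/new/changed/deleted
#'   records, warnings, errors, and whether the run committed.
#' @export
gdb_load <- function(db, table, records, mode = "dry_run") {
  mode <- match.arg(mode, gv_load_modes)
  if (!table %in% names(.gv_schema)) stop("no such table: ", table)
  rep <- new_load_report()
  snap <- gdb_snapshot(db)
  err <- tryCatch({
    validator <- .gv_validators[[table]]
    if (is.null(validator)) stop("no loader defined for table ", table)
    recs <- validator(db, records)
    rep$n_parsed <- nrow(recs)
    spec <- .gv_schema[[table]]
    key <- spec$key
    cur <- db$tables[[table]]
    rk <- gv_key_string(recs, key)
    if (anyDuplicated(rk)) {
      stop("duplicate key(s) within the input: ",
           paste(utils::head(unique(rk[duplicated(rk)]), 3L),
                 collapse = "; "))
    }
    idx <- match(rk, gv_key_string(cur, key))
    is_new <- is.na(idx)
    changed <- rep(FALSE, nrow(recs))
    if (any(!is_new)) {
      old <- cur[idx[!is_new], , drop = FALSE]
      changed[!is_new] <- gv_row_differs(recs[!is_new, , drop = FALSE],
                                         old, spec$payload)
    }
    keylab <- do.call(paste, c(unname(recs[key]), list(sep = "/")))

    if (mode == "delete") {
      hit <- !is_new
      if (any(is_new)) {
        rep$warnings <- c(rep$warnings, paste0(
          "not in store, cannot delete: ",
          paste(utils::head(keylab[is_new], 5L), collapse = ", ")))
      }
      drop_idx <- idx[hit]
      if (!is.null(spec$id)) {
        gv_check_unreferenced(db, table, cur[[spec$id]][drop_idx])
      }
      rep$n_deleted <- gv_delete_rows(
        db, table, seq_len(nrow(cur)) %in% drop_idx)
      rep$committed <- TRUE
      return(rep)
    }

    rep$n_new <- sum(is_new)
    rep$n_changed <- sum(changed)
    if (mode %in% c("dry_run", "compare")) {
      if (mode == "compare" && any(changed)) {
        rep$warnings <- c(rep$warnings, paste0(
          "differs from store: ",
          paste(utils::head(keylab[changed], 10L), collapse = ", ")))
      }
      return(rep)
    }

    # committing modes
    if (any(changed)) {
      if (mode == "commit") {
        rep$warnings <- c(rep$warnings, paste0(
          "changed record(s) NOT modified (commit only adds new rows): ",
          paste(utils::head(keylab[changed], 10L), collapse = ", ")))
      } else if (mode == "commit_replace") {
        drop_idx <- idx[changed]
        if (!is.null(spec$id)) {
          gv_check_unreferenced(db, table, cur[[spec$id]][drop_idx])
        }
        gv_delete_rows(db, table, seq_len(nrow(cur)) %in% drop_idx)
        gv_insert(db, table, recs[changed, , drop = FALSE])
      } else if (mode == "commit_update") {
        tab <- db$tables[[table]]
        rows <- idx[changed]
        for (col in spec$payload) {
          tab[[col]][rows] <- recs[[col]][changed]
        }
        tab$created[rows] <- gv_timestamp()
        db$tables[[table]] <- tab
      }
    }
    if (any(is_new)) gv_insert(db, table, recs[is_new, , drop = FALSE])
    rep$committed <- TRUE
    NULL
  }, error = function(e) conditionMessage(e))
  if (is.character(err)) {
    gdb_restore(db, snap)
    rep$errors <- c(rep$errors, err)
    rep$committed <- FALSE
  }
  rep
}

#' Resolve a (pedigree, person) name pair to a member id
#'
#' Canonical names resolve to themselves; alias pairs resolve through the
#' member-alias table to their target member, so samples named under an
#' alternative scheme (re-runs, lab relabellings) attach to the right
#' subject.
#'
#' @param db a `gdb` object.
#' @param pedigree,person character vectors (recycled).
#' @param must if `TRUE` (default) an unknown name is an error; otherwise
#'   `NA` is returned for it.
#' @return Integer vector of member ids.
#' @export
resolve_member <- function(db, pedigree, person, must = TRUE) {
  n <- max(length(pedigree), length(person))
  pedigree <- rep_len(as.character(pedigree), n)
  person <- rep_len(as.character(person), n)
  key <- paste(pedigree, person, sep = "\r")
  mem <- db$tables$members
  out <- mem$member_id[match(key, paste(mem$pedigree, mem$person,
                                        sep = "\r"))]
  al <- db$tables$member_aliases
  miss <- is.na(out)
  if (any(miss) && nrow(al)) {
    out[miss] <- al$member_id[match(key[miss],
                                    paste(al$alias_pedigree,
                                          al$alias_person, sep = "\r"))]
  }
  if (must && anyNA(out)) {
    bad <- unique(paste0(pedigree[is.na(out)], "/", person[is.na(out)]))
    stop("unknown member(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  out
}

#' Resolve marker names to marker ids
#'
#' Canonical marker names resolve to themselves and alias names (e.g. an
#' rsID retired by a dbSNP merge) resolve to the marker they now designate,
#' so a marker can be requested by either name.
#'
#' @inheritParams resolve_member
#' @param name character vector of marker names.
#' @return Integer vector of marker ids.
#' @export
resolve_marker <- function(db, name, must = TRUE) {
  name <- as.character(name)
  mk <- db$tables$markers
  out <- mk$marker_id[match(name, mk$name)]
  al <- db$tables$marker_aliases
  miss <- is.na(out)
  if (any(miss) && nrow(al)) {
    out[miss] <- al$marker_id[match(name[miss], al$alias_name)]
  }
  if (must && anyNA(out)) {
    stop("unknown marker(s): ",
         paste(utils::head(unique(name[is.na(out)]), 5L), collapse = ", "))
  }
  out
}

# Experiment / technology bookkeeping ---------------------------------------

gv_technology_id <- function(db, name, create = FALSE) {
  tech <- db$tables$technologies
  id <- tech$technology_id[match(name, tech$name)]
  if (is.na(id)) {
    if (!create) stop("unknown technology: ", name)
    id <- gv_insert(db, "technologies", data.frame(name = name))
  }
  id
}

gv_experiment_id <- function(db, name) {
  ex <- db$tables$experiments
  id <- ex$experiment_id[match(name, ex$name)]
  if (is.na(id)) stop("unknown experiment: ", name)
  id
}

#' Register an experiment (and its technology)
#'
#' An experiment is one batch of genotyping performed with one technology;
#' every stored genotype carries both keys.  The integer `trust` level
#' ranks experiments for conflict resolution: only calls from the most
#' trusted experiments reporting a non-missing genotype survive into the
#' merge (default 0 for all, i.e. no preference).
#'
#' @param db a `gdb` object.
#' @param name experiment name (unique).
#' @param technology technology name; registered on first use.
#' @param trust integer trust level.
#' @param date optional date string.
#' @return The experiment id, invisibly.
#' @export
gdb_create_experiment <- function(db, name, technology, trust = 0L,
                                  date = NA_character_) {
  ex <- db$tables$experiments
  if (name %in% ex$name) return(invisible(gv_experiment_id(db, name)))
  tid <- gv_technology_id(db, technology, create = TRUE)
  id <- gv_insert(db, "experiments",
                  data.frame(name = name, date = as.character(date),
                             technology_id = tid,
                             trust = as.integer(trust)))
  invisible(id)
}

#' @rdname gdb_create_experiment
#' @export
gdb_set_experiment_date <- function(db, name, date) {
  id <- gv_experiment_id(db, name)
  i <- match(id, db$tables$experiments$experiment_id)
  db$tables$experiments$date[i] <- as.character(date)
  db$tables$experiments$created[i] <- gv_timestamp()
  invisible(id)
}

#' Delete all genotype data of an experiment
#'
#' Removes every row-store genotype and every genotype block belonging to
#' the experiment; other experiments are untouched.  The experiment record
#' itself is kept (it can be re-populated).
#'
#' @param db a `gdb` object.
#' @param experiment experiment name.
#' @return The number of genotype records removed (row-store rows plus
#'   block records).
#' @export
gdb_delete_experiment <- function(db, experiment) {
  id <- gv_experiment_id(db, experiment)
  n1 <- gv_delete_rows(db, "genotypes",
                       db$tables$genotypes$experiment_id == id)
  n2 <- gv_delete_rows(db, "genotypeblocks",
                       db$tables$genotypeblocks$experiment_id == id)
  n1 + n2
}

#' Switch stored genotypes on or off
#'
#' Sets the per-record `active` flag on row-store genotypes, so data judged
#' unreliable can be hidden from merging and export without deleting it —
#' the store retains all original data.  Inactive rows are invisible to the
#' merge (when the merge policy honours active flags, the default).
#'
#' @param db a `gdb` object.
#' @param experiment experiment name.
#' @param markers optional character vector of marker names (aliases
#'   allowed) restricting the flagged rows.
#' @param members optional data frame with `pedigree`, `person` columns
#'   restricting the flagged rows.
#' @param active the flag value to set.
#' @return The number of genotype rows updated.
#' @export
gdb_set_active <- function(db, experiment, markers = NULL, members = NULL,
                           active = TRUE) {
  id <- gv_experiment_id(db, experiment)
  g <- db$tables$genotypes
  mask <- g$experiment_id == id
  if (!is.null(markers)) {
    mask <- mask & g$marker_id %in% resolve_marker(db, markers)
  }
  if (!is.null(members)) {
    mask <- mask & g$member_id %in%
      resolve_member(db, members$pedigree, members$person)
  }
  if (any(mask)) {
    g$active[mask] <- active
    g$created[mask] <- gv_timestamp()
    db$tables$genotypes <- g
  }
  sum(mask)
}

#' List markers lacking map information for a build
#'
#' @param db a `gdb` object.
#' @param build map-build tag.
#' @return Character vector of canonical marker names with no marker-info
#'   record for `build`.
#' @export
gdb_missing_marker_info <- function(db, build) {
  mk <- db$tables$markers
  mi <- db$tables$marker_info[db$tables$marker_info$build == build, ]
  mk$name[!(mk$marker_id %in% mi$marker_id)]
}
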