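#' Describe the column layout of a delimited input file
#'
#' Input files are plain columnar text; a column map names which column (by
#' 1-based position, or by header name when `header = TRUE`) carries each
#' required field, so arbitrary lab exports can be read without reshaping.
#'
#' @param delimiter `"tab"`, `"comma"` or `"whitespace"`.
#' @param skip number of leading rows to skip.
#' @param header whether the (post-skip) first row is a header.
#' @param columns named list mapping canonical field names (e.g. `marker`,
#'   `chromosome`, `bp`; or `pedigree`, `person`, `father`, `mother`,
#'   `sex`; or `sample`, `allele1`, `allele2`) to column positions or
#'   header names.
#' @param missing_codes genotype tokens normalized to the missing allele
#'   `"0"` on input.
#' @return An object of class `column_map`.
#' @export
column_map <- function(delimiter = c("whitespace", "tab", "comma"),
                       skip = 0L, header = FALSE, columns = list(),
                       missing_codes = c("-", "N", "NA", ".")) {
  structure(list(delimiter = match.arg(delimiter), skip = as.integer(skip),
                 header = isTRUE(header), columns = columns,
                 missing_codes = missing_codes),
            class = "column_map")
}

gv_sep <- function(delimiter) {
  switch(delimiter, tab = "\t", comma = ",", whitespace = " ")
}

# Read a delimited file into a data frame of character columns.
gv_read_file <- function(path, colmap) {
  d <- data.table::fread(
    path, sep = gv_sep(colmap$delimiter), skip = colmap$skip,
    header = colmap$header, colClasses = "character",
    data.table = FALSE, strip.white = TRUE)
  d
}

# Pick the mapped columns out of a raw table and give them canonical names.
gv_map_columns <- function(d, colmap, required, optional = character(0)) {
  cols <- colmap$columns
  miss <- setdiff(required, names(cols))
  if (length(miss)) {
    stop("column map lacks required field(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(unlist(cols))) {
    stop("column map assigns two fields to the same column")
  }
  out <- list()
  for (f in intersect(c(required, optional), names(cols))) {
    sel <- cols[[f]]
    out[[f]] <- if (is.character(sel)) d[[sel]] else d[[as.integer(sel)]]
    if (is.null(out[[f]])) stop("column '", sel, "' not found for ", f)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Accept a data frame (canonical columns) or a path + column map.
gv_input <- function(x, colmap, required, optional = character(0)) {
  if (is.data.frame(x)) {
    gv_need_cols(x, required, "input")
    return(x)
  }
  if (!is.character(x) || length(x) != 1L) {
    stop("input must be a data frame or a single file path")
  }
  if (is.null(colmap)) {
    colmap <- column_map(delimiter = "tab", header = TRUE,
                         columns = stats::setNames(
                           as.list(c(required, optional)),
                           c(required, optional)))
    d <- gv_read_file(x, colmap)
    keep <- intersect(c(required, optional), names(d))
    gv_need_cols(d, required, "input file")
    return(d[, keep, drop = FALSE])
  }
  gv_map_columns(gv_read_file(x, colmap), colmap, required, optional)
}

gv_apply_missing <- function(a, missing_codes) {
  a <- as.character(a)
  a[a %in% missing_codes] <- "0"
  a
}

#' Import targeted (row-per-genotype) data
#'
#' Loads genotype calls from a follow-up/targeted experiment into the
#' row-store, one record per (member, marker) call.  Three layouts are
#' accepted: two allele columns (`allele1`, `allele2`), one genotype column
#' (`genotype`, e.g. `"A/C"`), or wide format with one row per person and
#' one genotype column per marker (marker names in the header).  Subjects
#' are identified either by `pedigree` + `person` columns (member aliases
#' honoured) or by a `sample` column resolved through the samples table.
#'
#' Every marker name must already be registered (internal consistency of
#' marker information); an unknown marker, person or malformed genotype
#' rolls the whole run back.  Re-importing an identical call for the same
#' (member, marker, experiment) is a no-op; a *different* call for that
#' index raises a warning, is recorded in the report, and is stored as a
#' within-experiment duplicate so the merge and the agreement diagnostics
#' can see it.
#'
#' @param db a `gdb` object.
#' @param x data frame or file path.
#' @param experiment,technology experiment and technology names; the
#'   experiment must exist (see [gdb_create_experiment()]).
#' @param colmap a [column_map()] for file input.
#' @param mode `"dry_run"` or `"commit"`.
#' @param store_missing whether to store `0/0` calls as records (default
#'   `FALSE`: missing genotypes are not stored in the row representation).
#' @return A `load_report`; `n_new` counts inserted genotype rows.
#' @export
import_targeted_genotypes <- function(db, x, experiment, technology,
                                      colmap = NULL, mode = "dry_run",
                                      store_missing = FALSE) {
  mode <- match.arg(mode, c("dry_run", "commit"))
  rep <- new_load_report()
  snap <- gdb_snapshot(db)
  err <- tryCatch({
    eid <- gv_experiment_id(db, experiment)
    tid <- gv_technology_id(db, technology, create = TRUE)
    mc <- if (!is.null(colmap)) colmap$missing_codes else
      c("-", "N", "NA", ".")
    long <- gv_targeted_long(db, x, colmap)
    long$allele1 <- gv_apply_missing(long$allele1, mc)
    long$allele2 <- gv_apply_missing(long$allele2, mc)
    call <- normalize_call(long$allele1, long$allele2)
    marker_id <- resolve_marker(db, long$marker)
    if (!is.null(long$sample)) {
      smp <- db$tables$samples
      sid <- smp$sample_id[match(long$sample, smp$sample_name)]
      if (anyNA(sid)) {
        stop("unknown sample(s): ",
             paste(utils::head(unique(long$sample[is.na(sid)]), 5L),
                   collapse = ", "))
      }
      member_id <- smp$member_id[match(sid, smp$sample_id)]
    } else {
      member_id <- resolve_member(db, long$pedigree, long$person)
      sid <- rep(NA_integer_, nrow(long))
    }
    rep$n_parsed <- nrow(long)
    keep <- store_missing | call != GV_MISSING
    rows <- data.frame(member_id = member_id[keep],
                       marker_id = marker_id[keep],
                       experiment_id = eid, technology_id = tid,
                       sample_id = sid[keep],
                       allele1 = call_alleles(call[keep])[, 1L],
                       allele2 = call_alleles(call[keep])[, 2L],
                       active = TRUE, stringsAsFactors = FALSE)
    # duplicates against the store (same member/marker/experiment)
    g <- db$tables$genotypes
    old <- g[g$experiment_id == eid, , drop = FALSE]
    okey <- paste(old$member_id, old$marker_id, sep = "\r")
    rkey <- paste(rows$member_id, rows$marker_id, sep = "\r")
    oi <- match(rkey, okey)
    dup_same <- !is.na(oi) &
      rows$allele1 == old$allele1[ifelse(is.na(oi), 1L, oi)] &
      rows$allele2 == old$allele2[ifelse(is.na(oi), 1L, oi)]
    dup_diff <- !is.na(oi) & !dup_same
    if (any(dup_diff)) {
      mk <- db$tables$markers
      rep$warnings <- c(rep$warnings, paste0(
        "already in store with a different genotype (kept as duplicate ",
        "measurements): ",
        paste(utils::head(
          mk$name[match(rows$marker_id[dup_diff], mk$marker_id)], 10L),
          collapse = ", ")))
    }
    rows <- rows[!dup_same, , drop = FALSE]
    rep$n_changed <- sum(dup_diff)
    rep$n_new <- nrow(rows)
    if (mode == "commit") {
      if (nrow(rows)) gv_insert(db, "genotypes", rows)
      rep$committed <- TRUE
    }
    NULL
  }, error = function(e) conditionMessage(e))
  if (is.character(err)) {
    gdb_restore(db, snap)
    rep$errors <- c(rep$errors, err)
    rep$committed <- FALSE
  }
  rep
}

# Reshape the accepted targeted layouts into long (id, marker, a1, a2).
gv_targeted_long <- function(db, x, colmap) {
  if (!is.data.frame(x) && is.null(colmap)) {
    # headered tab-delimited file with canonical column names
    x <- gv_read_file(x, column_map(delimiter = "tab", header = TRUE))
  }
  if (is.data.frame(x) && all(c("marker", "allele1", "allele2")
                              %in% names(x))) {
    d <- x
  } else if (is.data.frame(x) && all(c("marker", "genotype") %in% names(x))) {
    g <- gv_split_genotype(x$genotype)
    d <- x
    d$allele1 <- g$a1
    d$allele2 <- g$a2
  } else if (is.data.frame(x)) {
    # wide: id column(s) + one column per marker
    idcols <- intersect(c("pedigree", "person", "sample"), names(x))
    if (!length(idcols)) {
      stop("targeted input needs marker/allele columns or id columns ",
           "plus per-marker genotype columns")
    }
    mcols <- setdiff(names(x), idcols)
    long <- do.call(rbind, lapply(mcols, function(mk) {
      g <- gv_split_genotype(x[[mk]])
      cbind(x[idcols], data.frame(marker = mk, allele1 = g$a1,
                                  allele2 = g$a2,
                                  stringsAsFactors = FALSE))
    }))
    d <- long
  } else {
    if (is.null(colmap)) stop("file input needs a column map")
    raw <- gv_read_file(x, colmap)
    cols <- colmap$columns
    if (all(c("allele1", "allele2") %in% names(cols))) {
      d <- gv_map_columns(raw, colmap, c("marker", "allele1", "allele2"),
                          c("pedigree", "person", "sample"))
    } else if ("genotype" %in% names(cols)) {
      d <- gv_map_columns(raw, colmap, c("marker", "genotype"),
                          c("pedigree", "person", "sample"))
      g <- gv_split_genotype(d$genotype)
      d$allele1 <- g$a1
      d$allele2 <- g$a2
    } else {
      # wide file: id columns mapped, every remaining column is a marker
      idmap <- gv_map_columns(raw, colmap, character(0),
                              c("pedigree", "person", "sample"))
      used <- vapply(colmap$columns, function(s)
        if (is.character(s)) match(s, names(raw)) else as.integer(s),
        integer(1))
      mcols <- setdiff(seq_along(raw), used)
      if (!colmap$header) {
        stop("wide targeted input needs a header row of marker names")
      }
      d <- do.call(rbind, lapply(mcols, function(ci) {
        g <- gv_split_genotype(raw[[ci]])
        cbind(idmap, data.frame(marker = names(raw)[ci], allele1 = g$a1,
                                allele2 = g$a2, stringsAsFactors = FALSE))
      }))
    }
  }
  if (!("sample" %in% names(d)) &&
      !all(c("pedigree", "person") %in% names(d))) {
    stop("targeted input must identify subjects by sample or ",
         "pedigree/person")
  }
  d
}

# --- genome-wide import base -----------------------------------------------

# Shared base for the per-sample-file, multi-sample-file and PLINK-binary
# importers: registers markers + map info, builds/reuses the layout index,
# then encodes and stores one block set per sample.  `get_calls(i)` must
# return a data frame (marker, allele1, allele2) or (marker, genotype)
# aligned with the mapping's marker set.
gv_import_blocks <- function(db, mapping, sample_names, get_calls,
                             experiment, technology, layout, block_size,
                             build, mode, missing_codes,
                             register_markers = TRUE) {
  rep <- new_load_report()
  snap <- gdb_snapshot(db)
  err <- tryCatch({
    eid <- gv_experiment_id(db, experiment)
    gv_technology_id(db, technology, create = TRUE)
    map <- mapping
    gv_need_cols(map, c("marker", "chromosome", "bp"), "marker mapping")
    map$chromosome <- parse_chromosome(map$chromosome)
    map$bp <- as.numeric(map$bp)
    if (register_markers) {
      newm <- setdiff(map$marker,
                      c(db$tables$markers$name,
                        db$tables$marker_aliases$alias_name))
      if (length(newm)) {
        r <- gdb_load(db, "markers", data.frame(name = newm), "commit")
        if (length(r$errors)) stop(r$errors[[1L]])
      }
    }
    map$marker_id <- resolve_marker(db, map$marker)
    mi <- data.frame(marker = map$marker, build = build,
                     chromosome = map$chromosome, bp = map$bp,
                     stringsAsFactors = FALSE)
    for (col in c("avg_cm", "female_cm", "male_cm")) {
      if (col %in% names(map)) mi[[col]] <- map[[col]]
    }
    r <- gdb_load(db, "marker_info", mi, "commit")
    if (length(r$errors)) stop(r$errors[[1L]])
    rep$warnings <- c(rep$warnings, r$warnings)
    gv_make_layout(db, layout, map$marker_id, map$chromosome, map$bp,
                   block_size)
    geom <- gv_layout_geometry(db, layout)

    smp <- db$tables$samples
    sids <- smp$sample_id[match(sample_names, smp$sample_name)]
    if (anyNA(sids)) {
      stop("unregistered sample(s): ",
           paste(utils::head(sample_names[is.na(sids)], 5L),
                 collapse = ", "))
    }
    rep$n_parsed <- length(sample_names)
    pieces <- vector("list", length(sample_names))
    for (i in seq_along(sample_names)) {
      calls <- get_calls(i)
      if (all(c("allele1", "allele2") %in% names(calls))) {
        a1 <- gv_apply_missing(calls$allele1, missing_codes)
        a2 <- gv_apply_missing(calls$allele2, missing_codes)
      } else if ("genotype" %in% names(calls)) {
        g <- gv_split_genotype(calls$genotype)
        a1 <- gv_apply_missing(g$a1, missing_codes)
        a2 <- gv_apply_missing(g$a2, missing_codes)
      } else stop("sample input needs allele1/allele2 or genotype columns")
      pos <- match(calls$marker, map$marker)
      if (nrow(calls) != nrow(map) || anyNA(pos) || anyDuplicated(pos)) {
        stop("sample '", sample_names[i], "' does not match the marker ",
             "mapping (", nrow(calls), " calls vs ", nrow(map),
             " mapped markers)")
      }
      cv <- normalize_call(a1, a2)
      pieces[[i]] <- gv_encode_sample_rows(
        geom, map$marker_id[pos], cv, sids[i], eid, layout)
    }
    rows <- as.data.frame(data.table::rbindlist(pieces),
                          stringsAsFactors = FALSE)
    if (!ncol(rows)) {
      rows <- gv_empty_table("genotypeblocks")
      rows$created <- NULL
    }
    if (mode == "commit") {
      nw <- withCallingHandlers(
        gv_insert_blocks(db, rows),
        warning = function(w) {
          rep$warnings <<- c(rep$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      rep$n_new <- nw
      rep$committed <- TRUE
    } else {
      key <- c("sample_id", "experiment_id", "layout", "chromosome",
               "block_index")
      rep$n_new <- sum(is.na(match(
        gv_key_string(rows, key),
        gv_key_string(db$tables$genotypeblocks, key))))
    }
    NULL
  }, error = function(e) conditionMessage(e))
  if (is.character(err)) {
    gdb_restore(db, snap)
    rep$errors <- c(rep$errors, err)
    rep$committed <- FALSE
  } else if (mode != "commit") {
    gdb_restore(db, snap)   # dry runs leave nothing behind, not even markers
  }
  rep
}

gv_read_mapping <- function(mapping, colmap) {
  gv_input(mapping, colmap, c("marker", "chromosome", "bp"),
           c("avg_cm", "female_cm", "male_cm"))
}

#' Import genome-wide data supplied as one file per sample
#'
#' The Illumina-style dialect: a marker mapping file (marker, chromosome,
#' base-pair position, optional genetic positions) plus one genotype file
#' per sample.  The mapping populates the marker table, per-build map info
#' and the block index of `layout`; each sample's calls are packed into
#' genotype blocks.  Samples must be registered beforehand; every sample
#' must carry exactly the mapping's marker set, and any error rolls the
#' whole run back.  Re-running an unchanged import writes nothing.
#'
#' @param db a `gdb` object.
#' @param mapping marker mapping: data frame or file path (see
#'   [column_map()]).
#' @param samples a named list (names are registered sample names) whose
#'   elements are each a file path, a data frame with columns
#'   `marker` + `allele1`/`allele2` (or `genotype`), or a zero-argument
#'   function returning such a data frame (lazy generation for large runs).
#' @param experiment,technology experiment (must exist) and technology.
#' @param layout name of the block layout; experiments genotyped on the
#'   same chip should share it.  Defaults to the experiment name.
#' @param block_size genotypes per block record.
#' @param build map-build tag for the mapping's positions.
#' @param map_colmap,sample_colmap [column_map()]s for file inputs.
#' @param mode `"dry_run"` or `"commit"`.
#' @return A `load_report`; `n_new` counts block records written.
#' @export
import_per_sample_files <- function(db, mapping, samples, experiment,
                                    technology = "Illumina",
                                    layout = experiment,
                                    block_size = 500L, build = "1",
                                    map_colmap = NULL,
                                    sample_colmap = NULL,
                                    mode = "dry_run") {
  mode <- match.arg(mode, c("dry_run", "commit"))
  map <- gv_read_mapping(mapping, map_colmap)
  mc <- if (!is.null(sample_colmap)) sample_colmap$missing_codes else
    c("-", "N", "NA", ".")
  get_calls <- function(i) {
    s <- samples[[i]]
    if (is.function(s)) s <- s()
    if (is.character(s)) {
      s <- gv_input(s, sample_colmap, "marker",
                    c("allele1", "allele2", "genotype"))
    }
    s
  }
  gv_import_blocks(db, map, names(samples), get_calls, experiment,
                   technology, layout, block_size, build, mode, mc)
}

#' Import genome-wide data supplied as one multi-sample file
#'
#' The Affymetrix-style dialect: one marker mapping file plus a single wide
#' genotype file holding a marker column and one genotype column per sample
#' (sample names in the header).  Shares the block-writing base of
#' [import_per_sample_files()], so the same logical data imported through
#' either dialect produces identical stored blocks.
#'
#' @inheritParams import_per_sample_files
#' @param x wide genotype table: data frame or file path; the first mapped
#'   column is `marker` (via `colmap`, default column 1), all remaining
#'   columns are samples.
#' @param colmap a [column_map()] for `x` when it is a path; must have
#'   `header = TRUE`.
#' @return A `load_report`.
#' @export
import_multi_sample_file <- function(db, x, mapping, experiment,
                                     technology = "Affymetrix",
                                     layout = experiment,
                                     block_size = 500L, build = "1",
                                     map_colmap = NULL, colmap = NULL,
                                     mode = "dry_run") {
  mode <- match.arg(mode, c("dry_run", "commit"))
  map <- gv_read_mapping(mapping, map_colmap)
  if (is.character(x)) {
    if (is.null(colmap)) {
      colmap <- column_map(delimiter = "tab", header = TRUE,
                           columns = list(marker = "marker"))
    }
    x <- gv_read_file(x, colmap)
  }
  mcol <- colmap$columns$marker %||% "marker"
  if (!is.character(mcol)) mcol <- names(x)[as.integer(mcol)]
  sample_names <- setdiff(names(x), mcol)
  mc <- if (!is.null(colmap)) colmap$missing_codes else
    c("-", "N", "NA", ".")
  get_calls <- function(i) {
    data.frame(marker = x[[mcol]], genotype = x[[sample_names[i]]],
               stringsAsFactors = FALSE)
  }
  gv_import_blocks(db, map, sample_names, get_calls, experiment,
                   technology, layout, block_size, build, mode, mc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import a PLINK 1 binary fileset
#'
#' Reads a bed/bim/fam trio (SNP-major binary v1).  The variant file
#' populates markers, per-build map info and the block index; the pedigree
#' file populates members and samples (one sample per individual, named
#' `FID:IID`) and its phenotype column becomes one qualitative trait; the
#' packed genotypes are decoded into genotype blocks.  Individual-major
#' files are not supported.
#'
#' @inheritParams import_per_sample_files
#' @param bed,bim,fam paths to the three files.
#' @param trait name under which the fam phenotype column is stored
#'   (values `-9`/`0` are treated as missing and skipped).
#' @return A `load_report`.
#' @export
import_plink_binary <- function(db, bed, bim, fam, experiment,
                                technology = "PLINK",
                                layout = experiment, block_size = 500L,
                                build = "1", trait = "affection",
                                mode = "dry_run") {
  mode <- match.arg(mode, c("dry_run", "commit"))
  rep <- new_load_report()
  snap <- gdb_snapshot(db)
  err <- tryCatch({
    px <- read_plink_bed(bed, bim, fam)
    fm <- px$fam
    mem <- data.frame(pedigree = fm$pedigree, person = fm$person,
                      father = fm$father, mother = fm$mother,
                      sex = fm$sex, stringsAsFactors = FALSE)
    r <- gdb_load(db, "members", mem, "commit")
    if (length(r$errors)) stop(r$errors[[1L]])
    sample_names <- paste(fm$pedigree, fm$person, sep = ":")
    r <- gdb_load(db, "samples",
                  data.frame(sample_name = sample_names,
                             pedigree = fm$pedigree, person = fm$person,
                             stringsAsFactors = FALSE), "commit")
    if (length(r$errors)) stop(r$errors[[1L]])
    ph <- fm$phenotype
    has_ph <- !is.na(ph) & !(ph %in% c("-9", "0"))
    if (any(has_ph)) {
      r <- load_trait(db, data.frame(pedigree = fm$pedigree[has_ph],
                                     person = fm$person[has_ph],
                                     value = ph[has_ph],
                                     stringsAsFactors = FALSE),
                      trait = trait, kind = "qualitative", mode = "commit")
      if (length(r$errors)) stop(r$errors[[1L]])
    }
    map <- data.frame(marker = px$bim$marker,
                      chromosome = px$bim$chromosome, bp = px$bim$bp,
                      avg_cm = px$bim$cm, stringsAsFactors = FALSE)
    get_calls <- function(i) {
      data.frame(marker = px$bim$marker, genotype = px$calls[i, ],
                 stringsAsFactors = FALSE)
    }
    sub <- gv_import_blocks(db, map, sample_names, get_calls, experiment,
                            technology, layout, block_size, build,
                            mode, character(0))
    if (length(sub$errors)) stop(sub$errors[[1L]])
    rep$n_parsed <- sub$n_parsed
    rep$n_new <- sub$n_new
    rep$warnings <- c(rep$warnings, sub$warnings)
    rep$committed <- sub$committed
    NULL
  }, error = function(e) conditionMessage(e))
  if (is.character(err)) {
    gdb_restore(db, snap)
    rep$errors <- c(rep$errors, err)
    rep$committed <- FALSE
  }
  if (mode == "dry_run") gdb_restore(db, snap)
  rep
}
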