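#' Describe a data-extraction subset
#'
#' Collects every filter the extraction step supports: pedigree and person
#' include/exclude lists (exclusion wins on overlap), trait-value filters,
#' pedigree completion (close the selected pool over pedigree
#' co-membership so family structures stay intact), marker name lists,
#' chromosome and position-range selection (base pairs or centimorgans,
#' both ends inclusive) against a named map build, experiment/technology
#' restriction, per-member exclusion ranges masked to `0/0` before
#' merging, and dropping of markers left with no observation.
#'
#' @param include_pedigrees,exclude_pedigrees character vectors of
#'   pedigree names.
#' @param include_persons,exclude_persons data frames with `pedigree`,
#'   `person` columns.
#' @param complete_pedigrees close the member pool over pedigree
#'   co-membership after the other member filters.
#' @param trait_filters named list: trait name -> either a vector of
#'   accepted values or a predicate function on the (character) values;
#'   quantitative traits are passed to predicates as numeric.
#' @param markers character vector of marker names (aliases allowed).
#' @param chromosomes integer vector of chromosomes to keep.
#' @param ranges data frame with `chromosome`, `lo`, `hi` and optionally
#'   `units` (`"bp"`, the default, or `"cM"`).
#' @param experiments,technologies character vectors restricting which
#'   experiments'/technologies' genotypes are read.
#' @param typed_in character vector of experiment names; keep only members
#'   with at least one genotype in one of them.
#' @param drop_untyped_markers drop markers with no observation among the
#'   selected members.
#' @param exclusions list of exclusion ranges, each a list with
#'   `chromosome`, `lo`, `hi` and optionally `members` (a data frame of
#'   `pedigree`, `person`); calls inside are masked to `0/0` (for the
#'   listed members, or everyone).
#' @param build map-build tag whose positions drive every positional
#'   filter (the *current* view of the genome, not the storage layout).
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(include_pedigrees = NULL,
                           exclude_pedigrees = NULL,
                           include_persons = NULL, exclude_persons = NULL,
                           complete_pedigrees = FALSE,
                           trait_filters = NULL, markers = NULL,
                           chromosomes = NULL, ranges = NULL,
                           experiments = NULL, technologies = NULL,
                           typed_in = NULL,
                           drop_untyped_markers = FALSE,
                           exclusions = NULL, build = "1") {
  if (!is.null(ranges)) {
    gv_need_cols(ranges, c("chromosome", "lo", "hi"), "ranges")
    if (!"units" %in% names(ranges)) ranges$units <- "bp"
    if (!all(ranges$units %in% c("bp", "cM"))) {
      stop("range units must be 'bp' or 'cM'")
    }
    if (any(ranges$lo > ranges$hi)) stop("range lo exceeds hi")
  }
  if (!is.null(exclusions)) {
    for (e in exclusions) {
      if (!all(c("chromosome", "lo", "hi") %in% names(e))) {
        stop("each exclusion needs chromosome, lo, hi")
      }
      if (e$lo > e$hi) stop("exclusion lo exceeds hi")
    }
  }
  structure(list(include_pedigrees = include_pedigrees,
                 exclude_pedigrees = exclude_pedigrees,
                 include_persons = include_persons,
                 exclude_persons = exclude_persons,
                 complete_pedigrees = isTRUE(complete_pedigrees),
                 trait_filters = trait_filters, markers = markers,
                 chromosomes = chromosomes, ranges = ranges,
                 experiments = experiments, technologies = technologies,
                 typed_in = typed_in,
                 drop_untyped_markers = isTRUE(drop_untyped_markers),
                 exclusions = exclusions, build = build),
            class = "selection_spec")
}

gv_person_key <- function(df) paste(df$pedigree, df$person, sep = "\r")

#' Select the member subset of an extraction
#'
#' Applies include/exclude pedigree and person filters (exclusion wins),
#' trait-value filters, the typed-in-experiment restriction, and finally —
#' if requested — pedigree completion, which closes the pool over
#' pedigree co-membership of any selected member so that family
#' structures remain analyzable.
#'
#' @param db a `gdb` object.
#' @param spec a [selection_spec()].
#' @return The selected rows of the members table, ordered by
#'   (pedigree, person).
#' @export
select_members <- function(db, spec) {
  mem <- db$tables$members
  known_ped <- unique(mem$pedigree)
  bad <- c(setdiff(spec$include_pedigrees, known_ped),
           setdiff(spec$exclude_pedigrees, known_ped))
  keys <- gv_person_key(mem)
  for (df in list(spec$include_persons, spec$exclude_persons)) {
    if (!is.null(df)) {
      miss <- !(gv_person_key(df) %in% keys)
      if (any(miss)) {
        bad <- c(bad, paste0(df$pedigree[miss], "/", df$person[miss]))
      }
    }
  }
  if (length(bad)) {
    stop("selection names unknown pedigree(s)/person(s): ",
         paste(unique(bad), collapse = ", "))
  }
  keep <- rep(TRUE, nrow(mem))
  if (!is.null(spec$include_pedigrees) || !is.null(spec$include_persons)) {
    keep <- rep(FALSE, nrow(mem))
    if (!is.null(spec$include_pedigrees)) {
      keep <- keep | mem$pedigree %in% spec$include_pedigrees
    }
    if (!is.null(spec$include_persons)) {
      keep <- keep | keys %in% gv_person_key(spec$include_persons)
    }
  }
  if (!is.null(spec$exclude_pedigrees)) {
    keep <- keep & !(mem$pedigree %in% spec$exclude_pedigrees)
  }
  if (!is.null(spec$exclude_persons)) {
    keep <- keep & !(keys %in% gv_person_key(spec$exclude_persons))
  }
  if (!is.null(spec$trait_filters)) {
    tm <- db$tables$traitmeta
    tr <- db$tables$traits
    for (tn in names(spec$trait_filters)) {
      tid <- tm$trait_id[match(tn, tm$name)]
      if (is.na(tid)) stop("unknown trait in filter: ", tn)
      vals <- tr[tr$trait_id == tid, , drop = FALSE]
      v <- vals$value
      if (tm$kind[match(tid, tm$trait_id)] == "quantitative") {
        v <- as.numeric(v)
      }
      f <- spec$trait_filters[[tn]]
      ok_members <- if (is.function(f)) {
        vals$member_id[which(f(v))]
      } else if (is.numeric(v)) {
        vals$member_id[v %in% suppressWarnings(as.numeric(f))]
      } else {
        vals$member_id[v %in% as.character(f)]
      }
      keep <- keep & mem$member_id %in% ok_members
    }
  }
  if (!is.null(spec$typed_in)) {
    eids <- vapply(spec$typed_in, gv_experiment_id, integer(1), db = db)
    g <- db$tables$genotypes
    typed <- g$member_id[g$experiment_id %in% eids]
    gb <- db$tables$genotypeblocks
    gb <- gb[gb$experiment_id %in% eids, , drop = FALSE]
    smp <- db$tables$samples
    typed <- c(typed, smp$member_id[match(gb$sample_id, smp$sample_id)])
    keep <- keep & mem$member_id %in% typed
  }
  if (spec$complete_pedigrees) {
    peds <- unique(mem$pedigree[keep])
    keep <- mem$pedigree %in% peds
  }
  out <- mem[keep, , drop = FALSE]
  out[order(out$pedigree, out$person), , drop = FALSE]
}

#' Select and order the marker subset of an extraction
#'
#' Resolves requested names through marker aliases, then filters by
#' chromosome and by base-pair or centimorgan ranges using the map
#' positions of the spec's *build* — the current view of the genome, not
#' the chromosome a marker was stored under, so a marker remapped between
#' builds is found at its new location.  Markers lacking a centimorgan
#' position are excluded from cM-range selection with a warning.  Output
#' is ordered by (chromosome, bp, name): total and deterministic.
#'
#' @param db a `gdb` object.
#' @param spec a [selection_spec()].
#' @return A data frame with `marker_id`, `name`, `chromosome`, `bp`,
#'   `avg_cm` in map order.
#' @export
select_markers <- function(db, spec) {
  mk <- db$tables$markers
  mi <- db$tables$marker_info
  mi <- mi[mi$build == spec$build, , drop = FALSE]
  if (!is.null(spec$markers)) {
    ids <- resolve_marker(db, spec$markers)
    noinfo <- !(ids %in% mi$marker_id)
    if (any(noinfo)) {
      stop("marker(s) with no map info in build '", spec$build, "': ",
           paste(unique(spec$markers[noinfo]), collapse = ", "))
    }
    mi <- mi[mi$marker_id %in% ids, , drop = FALSE]
  }
  if (!is.null(spec$chromosomes)) {
    mi <- mi[mi$chromosome %in% parse_chromosome(spec$chromosomes), ,
             drop = FALSE]
  }
  if (!is.null(spec$ranges)) {
    hit <- rep(FALSE, nrow(mi))
    warned_cm <- FALSE
    for (i in seq_len(nrow(spec$ranges))) {
      r <- spec$ranges[i, ]
      chr <- parse_chromosome(r$chromosome)
      if (identical(r$units, "cM")) {
        nocm <- mi$chromosome == chr & is.na(mi$avg_cm)
        if (any(nocm) && !warned_cm) {
          warning(sum(nocm), " marker(s) without a cM position excluded ",
                  "from cM-range selection", call. = FALSE)
          warned_cm <- TRUE
        }
        hit <- hit | (mi$chromosome == chr & !is.na(mi$avg_cm) &
                        mi$avg_cm >= r$lo & mi$avg_cm <= r$hi)
      } else {
        hit <- hit | (mi$chromosome == chr & mi$bp >= r$lo &
                        mi$bp <= r$hi)
      }
    }
    mi <- mi[hit, , drop = FALSE]
  }
  out <- data.frame(marker_id = mi$marker_id,
                    name = mk$name[match(mi$marker_id, mk$marker_id)],
                    chromosome = mi$chromosome, bp = mi$bp,
                    avg_cm = mi$avg_cm, stringsAsFactors = FALSE)
  out[order(out$chromosome, out$bp, out$name), , drop = FALSE]
}

#' Mask calls falling in exclusion ranges
#'
#' Sets to `0/0` every call whose marker lies inside one of the spec's
#' exclusion ranges (for the members listed on the range, or all members
#' when none are listed).  Applied to the long call stream after the
#' inclusion filters and before conflict resolution, so excluded
#' measurements can neither win nor cause conflicts.
#'
#' @param calls long data frame with `member_id`, `marker_id`, `call`.
#' @param markers marker map as returned by [select_markers()].
#' @param exclusions the `exclusions` element of a [selection_spec()].
#' @param db a `gdb` object (needed to resolve member names on ranges).
#' @return `calls` with masked entries.
#' @export
apply_exclusions <- function(calls, markers, exclusions, db = NULL) {
  if (is.null(exclusions) || !length(exclusions) || !nrow(calls)) {
    return(calls)
  }
  chr <- markers$chromosome[match(calls$marker_id, markers$marker_id)]
  bp <- markers$bp[match(calls$marker_id, markers$marker_id)]
  for (e in exclusions) {
    mask <- !is.na(chr) & chr == parse_chromosome(e$chromosome) &
      bp >= e$lo & bp <= e$hi
    if (!is.null(e$members)) {
      if (is.null(db)) stop("member-specific exclusions need the database")
      ids <- resolve_member(db, e$members$pedigree, e$members$person)
      mask <- mask & calls$member_id %in% ids
    }
    calls$call[mask] <- GV_MISSING
  }
  calls
}
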