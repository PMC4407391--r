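.datatable.aware <- TRUE

#' Merge policy for multi-experiment reconciliation
#'
#' Governs how multiple stored calls for the same (member, marker) collapse
#' to one exported genotype: per-experiment integer trust levels (optionally
#' overridden per marker), whether per-record active flags hide data, and
#' whether a member's preferred sample silences their other samples.
#'
#' @param trust named integer vector, experiment name -> trust level;
#'   experiments not named keep their stored trust.
#' @param overrides data frame with `experiment`, `marker`, `trust`
#'   columns; a matching override beats the experiment-level trust (it may
#'   be lower, demoting a marker within an otherwise trusted experiment).
#' @param honor_active drop genotype rows whose active flag is off.
#' @param honor_preferred_sample when a member has a preferred sample, use
#'   only that sample's calls.
#' @return An object of class `merge_policy`.
#' @export
merge_policy <- function(trust = NULL, overrides = NULL,
                         honor_active = TRUE,
                         honor_preferred_sample = TRUE) {
  if (!is.null(overrides)) {
    gv_need_cols(overrides, c("experiment", "marker", "trust"),
                 "trust overrides")
  }
  structure(list(trust = trust, overrides = overrides,
                 honor_active = isTRUE(honor_active),
                 honor_preferred_sample = isTRUE(honor_preferred_sample)),
            class = "merge_policy")
}

#' Apply an allele relabelling map to calls
#'
#' Each allele is replaced if the map names it, otherwise kept; the result
#' is re-normalized, and `0/0` is a fixed point.  The map must be
#' injective (two alleles may not collapse onto one).
#'
#' @param calls character vector of normalized calls.
#' @param map data frame with `from_allele`, `to_allele` columns (one
#'   experiment/marker's map).
#' @return Character vector of remapped, normalized calls.
#' @examples
#' apply_allele_map("1/2", data.frame(from_allele = c("1", "2"),
#'                                    to_allele = c("A", "C")))  # "A/C"
#' @export
apply_allele_map <- function(calls, map) {
  if (is.null(map) || !nrow(map)) return(calls)
  if (anyDuplicated(map$from_allele) || anyDuplicated(map$to_allele) ||
      any(map$from_allele == "0") || any(map$to_allele == "0")) {
    stop("allele map must be injective and may not touch the missing code")
  }
  al <- call_alleles(calls)
  remap <- function(a) {
    i <- match(a, map$from_allele)
    ifelse(is.na(i), a, map$to_allele[i])
  }
  normalize_call(remap(al[, 1L]), remap(al[, 2L]))
}

#' Resolve multiple calls for one (member, marker) to a single genotype
#'
#' Missing (`0/0`) measurements are discarded first; if nothing remains the
#' result is missing without conflict.  Among the remaining calls only
#' those at the maximal trust level survive; if all survivors agree, that
#' common value is the result, otherwise the genotype is masked to `0/0`
#' and flagged as a conflict (to be recorded in the conflict log).  The
#' function is total, order-independent, and never invents a genotype: the
#' result is one of the input calls or `0/0`.
#'
#' @param calls character vector of normalized calls (allele maps already
#'   applied, inactive rows already removed).
#' @param trust integer vector of trust levels, recycled along `calls`.
#' @return A list with `call` (character) and `conflict` (logical).
#' @examples
#' resolve_calls(c("0/0", "A/C"))            # A/C, no conflict
#' resolve_calls(c("1/2", "G/T"))            # 0/0, conflict
#' resolve_calls(c("1/2", "G/T"), c(1, 2))   # G/T, no conflict
#' @export
resolve_calls <- function(calls, trust = 0L) {
  calls <- as.character(calls)
  trust <- rep_len(as.integer(trust), length(calls))
  keep <- calls != GV_MISSING
  calls <- calls[keep]
  trust <- trust[keep]
  if (!length(calls)) return(list(call = GV_MISSING, conflict = FALSE))
  top <- calls[trust == max(trust)]
  if (length(unique(top)) == 1L) {
    list(call = top[[1L]], conflict = FALSE)
  } else {
    list(call = GV_MISSING, conflict = TRUE)
  }
}

# Vectorized resolution over a long call table; one output row per
# (member_id, marker_id).  Uses data.table grouping but the per-group rule
# is exactly resolve_calls().
gv_resolve_table <- function(long) {
  dt <- data.table::as.data.table(long)
  if (!"experiment" %in% names(dt)) {
    dt$experiment <- as.character(dt$experiment_id)
  }
  known <- dt[dt$call != GV_MISSING, ]
  if (nrow(known)) {
    res <- known[, {
      top <- call[trust == max(trust)]
      u <- unique(top)
      list(call = if (length(u) == 1L) u else GV_MISSING,
           conflict = length(u) > 1L,
           detail = if (length(u) > 1L)
             paste(paste0(experiment, ":", call), collapse = "; ")
           else NA_character_)
    }, by = c("member_id", "marker_id")]
  } else {
    res <- data.table::data.table(member_id = integer(0),
                                  marker_id = integer(0),
                                  call = character(0),
                                  conflict = logical(0),
                                  detail = character(0))
  }
  # pairs seen only as 0/0 resolve to missing without conflict
  allpairs <- unique(dt[, c("member_id", "marker_id")])
  res <- merge(allpairs, res, by = c("member_id", "marker_id"),
               all.x = TRUE)
  res$call[is.na(res$call)] <- GV_MISSING
  res$conflict[is.na(res$conflict)] <- FALSE
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Select which sample's calls represent a member
#'
#' When one person has several samples (re-runs, duplicate controls), a
#' preferred sample — if one is flagged — silences the others; otherwise
#' all samples' calls pass through to conflict resolution, where
#' within-member discordance is handled like any other conflict.
#'
#' @param calls data frame of one member's calls with a `sample_id` column
#'   (`NA` for calls not attributed to a sample).
#' @param samples the samples table rows of this member.
#' @param honor_preferred whether preferred flags are honoured.
#' @return The filtered `calls` data frame.
#' @export
select_sample_calls <- function(calls, samples, honor_preferred = TRUE) {
  if (!honor_preferred || !nrow(samples)) return(calls)
  pref <- samples$sample_id[samples$preferred %in% TRUE]
  if (!length(pref)) return(calls)
  keep <- is.na(calls$sample_id) | calls$sample_id %in% pref
  calls[keep, , drop = FALSE]
}

# Apply preferred-sample silencing across a long call table.
gv_prefer_samples <- function(long, samples) {
  pref <- samples[samples$preferred %in% TRUE, , drop = FALSE]
  if (!nrow(pref)) return(long)
  has_pref <- long$member_id %in% pref$member_id
  keep <- !has_pref | is.na(long$sample_id) |
    long$sample_id %in% pref$sample_id
  long[keep, , drop = FALSE]
}

# Apply stored allele maps (per experiment x marker) to a long call table.
gv_apply_allele_maps <- function(db, long) {
  am <- db$tables$allele_map
  if (!nrow(am) || !nrow(long)) return(long)
  lk <- paste(long$experiment_id, long$marker_id, sep = "\r")
  ak <- paste(am$experiment_id, am$marker_id, sep = "\r")
  todo <- lk %in% ak
  if (!any(todo)) return(long)
  for (k in unique(lk[todo])) {
    rows <- lk == k
    map <- am[ak == k, , drop = FALSE]
    long$call[rows] <- apply_allele_map(long$call[rows], map)
  }
  long
}

# Effective trust per row: experiment trust, overridden per (exp, marker).
gv_effective_trust <- function(db, long, policy) {
  ex <- db$tables$experiments
  trust <- ex$trust[match(long$experiment_id, ex$experiment_id)]
  if (!is.null(policy$trust)) {
    eid <- vapply(names(policy$trust), gv_experiment_id, integer(1),
                  db = db)
    i <- match(long$experiment_id, eid)
    trust <- ifelse(is.na(i), trust, as.integer(policy$trust)[i])
  }
  if (!is.null(policy$overrides)) {
    ov <- policy$overrides
    oe <- vapply(as.character(ov$experiment), gv_experiment_id,
                 integer(1), db = db)
    om <- resolve_marker(db, ov$marker)
    i <- match(paste(long$experiment_id, long$marker_id, sep = "\r"),
               paste(oe, om, sep = "\r"))
    trust <- ifelse(is.na(i), trust, as.integer(ov$trust)[i])
  }
  trust
}

#' Cross-tabulate two experiments' calls into an agreement matrix
#'
#' Cell (g_a, g_b) counts the members whose (post-remapping) genotype was
#' g_a in the first experiment and g_b in the second; a member typed in
#' one experiment only appears in the other's `0/0` row/column.  The first
#' experiment labels the rows.  Off-diagonal non-missing mass is exactly
#' the set of members that conflict resolution (at equal trust) would mask.
#'
#' @param calls_a,calls_b character vectors of normalized calls, aligned
#'   by member.
#' @param experiments optional length-2 character vector of experiment
#'   names used as dimension names.
#' @return An integer matrix of class `agreement_matrix`, genotype labels
#'   ordered `0/0` first then by allele code.
#' @export
agreement_matrix <- function(calls_a, calls_b, experiments = NULL) {
  stopifnot(length(calls_a) == length(calls_b))
  lev <- gv_sort_calls(c(calls_a, calls_b, GV_MISSING))
  tab <- table(factor(calls_a, levels = lev),
               factor(calls_b, levels = lev))
  m <- matrix(as.integer(tab), nrow = length(lev),
              dimnames = list(lev, lev))
  if (!is.null(experiments)) {
    names(dimnames(m)) <- experiments
  }
  structure(m, class = c("agreement_matrix", class(m)))
}

#' @export
print.agreement_matrix <- function(x, ...) {
  y <- x
  class(y) <- "matrix"
  print(y)
  invisible(x)
}

#' Agreement matrix between two stored experiments
#'
#' Builds the member-aligned call vectors of both experiments at the given
#' marker(s) (row store and block store alike, allele maps applied, calls
#' within one experiment resolved first) and cross-tabulates them.
#' Members with a record in either experiment are counted; absence in the
#' other experiment counts as `0/0`.
#'
#' @param db a `gdb` object.
#' @param exp_a,exp_b distinct experiment names; `exp_a` labels the rows.
#' @param markers optional marker name vector (default: all markers
#'   measured by both).
#' @param apply_maps whether stored allele maps are applied first.
#' @return An `agreement_matrix` (summed over the markers).
#' @export
gdb_agreement <- function(db, exp_a, exp_b, markers = NULL,
                          apply_maps = TRUE) {
  if (identical(exp_a, exp_b)) {
    stop("agreement requires two distinct experiments")
  }
  ea <- gv_experiment_id(db, exp_a)
  eb <- gv_experiment_id(db, exp_b)
  mids <- if (is.null(markers)) db$tables$markers$marker_id else
    resolve_marker(db, markers)
  long <- gv_gather_calls(db, marker_ids = mids,
                          experiment_ids = c(ea, eb))
  if (apply_maps) long <- gv_apply_allele_maps(db, long)
  per_exp <- function(eid) {
    sub <- long[long$experiment_id == eid, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(member_id = integer(0), marker_id = integer(0),
                        call = character(0)))
    }
    sub$trust <- 0L
    gv_resolve_table(sub)[, c("member_id", "marker_id", "call")]
  }
  a <- per_exp(ea)
  b <- per_exp(eb)
  key <- union(paste(a$member_id, a$marker_id),
               paste(b$member_id, b$marker_id))
  ca <- a$call[match(key, paste(a$member_id, a$marker_id))]
  cb <- b$call[match(key, paste(b$member_id, b$marker_id))]
  ca[is.na(ca)] <- GV_MISSING
  cb[is.na(cb)] <- GV_MISSING
  agreement_matrix(ca, cb, experiments = c(exp_a, exp_b))
}

# Gather all stored calls (row store + block store) as a long table:
# member_id, marker_id, experiment_id, sample_id, call, active.
gv_gather_calls <- function(db, marker_ids, member_ids = NULL,
                            experiment_ids = NULL, technology_ids = NULL,
                            honor_active = TRUE) {
  g <- db$tables$genotypes
  if (!is.null(experiment_ids)) {
    g <- g[g$experiment_id %in% experiment_ids, , drop = FALSE]
  }
  if (!is.null(technology_ids)) {
    g <- g[g$technology_id %in% technology_ids, , drop = FALSE]
  }
  g <- g[g$marker_id %in% marker_ids, , drop = FALSE]
  if (!is.null(member_ids)) {
    g <- g[g$member_id %in% member_ids, , drop = FALSE]
  }
  if (honor_active) g <- g[g$active, , drop = FALSE]
  rows <- data.frame(member_id = g$member_id, marker_id = g$marker_id,
                     experiment_id = g$experiment_id,
                     sample_id = g$sample_id,
                     call = normalize_call(g$allele1, g$allele2),
                     stringsAsFactors = FALSE)
  sample_ids <- NULL
  if (!is.null(member_ids)) {
    smp <- db$tables$samples
    sample_ids <- smp$sample_id[smp$member_id %in% member_ids]
  }
  blocks <- gv_fetch_block_calls(db, marker_ids, sample_ids,
                                 experiment_ids)
  if (!is.null(member_ids) && nrow(blocks)) {
    blocks <- blocks[blocks$member_id %in% member_ids, , drop = FALSE]
  }
  if (!is.null(technology_ids) && nrow(blocks)) {
    ex <- db$tables$experiments
    bt <- ex$technology_id[match(blocks$experiment_id, ex$experiment_id)]
    blocks <- blocks[bt %in% technology_ids, , drop = FALSE]
  }
  out <- rbind(rows, blocks[, names(rows), drop = FALSE])
  out
}
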