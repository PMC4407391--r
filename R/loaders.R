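# Entity validators: take raw input records, resolve references against the
# store, enforce invariants, and return canonical rows (key + payload
# columns) ready for the gdb_load diff.  Any violation stop()s, which the
# load protocol turns into a rolled-back run.

gv_blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (trimws(x) == "" | x == "0")] <- NA_character_
  x
}

gv_need_cols <- function(records, cols, what) {
  miss <- setdiff(cols, names(records))
  if (length(miss)) {
    stop(what, " input lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
}

# Parentage must be cycle-free: a member may never be its own ancestor.
gv_check_pedigree_cycles <- function(key, father_key, mother_key) {
  parent <- list(match(father_key, key), match(mother_key, key))
  n <- length(key)
  # Kahn-style elimination: repeatedly drop members all of whose (in-set)
  # parents are already dropped; leftovers lie on a cycle.
  alive <- rep(TRUE, n)
  repeat {
    p1 <- parent[[1]]; p2 <- parent[[2]]
    can_drop <- alive &
      (is.na(p1) | !alive[ifelse(is.na(p1), 1L, p1)]) &
      (is.na(p2) | !alive[ifelse(is.na(p2), 1L, p2)])
    if (!any(can_drop)) break
    alive[can_drop] <- FALSE
  }
  if (any(alive)) {
    stop("cyclic parentage involving: ",
         paste(utils::head(gsub("\r", "/", key[alive]), 5L),
               collapse = ", "))
  }
  invisible(TRUE)
}

.gv_validators <- list()

.gv_validators$members <- function(db, records) {
  gv_need_cols(records, c("pedigree", "person"), "members")
  out <- data.frame(
    pedigree = as.character(records$pedigree),
    person = as.character(records$person),
    father = gv_blank_to_na(if ("father" %in% names(records))
      records$father else NA),
    mother = gv_blank_to_na(if ("mother" %in% names(records))
      records$mother else NA),
    sex = parse_sex(if ("sex" %in% names(records)) records$sex else NA),
    stringsAsFactors = FALSE)
  if (anyNA(out$pedigree) || anyNA(out$person)) {
    stop("members input has missing pedigree or person names")
  }
  # parents must name members of the same pedigree, in the file or the store
  cur <- db$tables$members
  key <- c(paste(out$pedigree, out$person, sep = "\r"),
           paste(cur$pedigree, cur$person, sep = "\r"))
  fa <- c(paste(out$pedigree, out$father, sep = "\r"),
          paste(cur$pedigree, cur$father, sep = "\r"))
  mo <- c(paste(out$pedigree, out$mother, sep = "\r"),
          paste(cur$pedigree, cur$mother, sep = "\r"))
  fa[is.na(c(out$father, cur$father))] <- NA
  mo[is.na(c(out$mother, cur$mother))] <- NA
  unknown <- c(fa, mo)
  unknown <- unknown[!is.na(unknown) & !(unknown %in% key)]
  if (length(unknown)) {
    stop("parent name(s) not found in their pedigree: ",
         paste(utils::head(unique(gsub("\r", "/", unknown)), 5L),
               collapse = ", "))
  }
  keep <- !duplicated(key)
  gv_check_pedigree_cycles(key[keep], fa[keep], mo[keep])
  out
}

.gv_validators$member_aliases <- function(db, records) {
  gv_need_cols(records,
               c("alias_pedigree", "alias_person", "pedigree", "person"),
               "member alias")
  mem <- db$tables$members
  akey <- paste(records$alias_pedigree, records$alias_person, sep = "\r")
  clash <- akey %in% paste(mem$pedigree, mem$person, sep = "\r")
  if (any(clash)) {
    stop("alias name(s) collide with canonical member names: ",
         paste(utils::head(gsub("\r", "/", akey[clash]), 5L),
               collapse = ", "))
  }
  ids <- mem$member_id[match(paste(records$pedigree, records$person,
                                   sep = "\r"),
                             paste(mem$pedigree, mem$person, sep = "\r"))]
  if (anyNA(ids)) {
    stop("alias target(s) are not registered members: ",
         paste(utils::head(paste0(records$pedigree[is.na(ids)], "/",
                                  records$person[is.na(ids)]), 5L),
               collapse = ", "))
  }
  data.frame(alias_pedigree = as.character(records$alias_pedigree),
             alias_person = as.character(records$alias_person),
             member_id = ids, stringsAsFactors = FALSE)
}

.gv_validators$samples <- function(db, records) {
  gv_need_cols(records, c("sample_name", "pedigree", "person"), "samples")
  ids <- resolve_member(db, records$pedigree, records$person)
  pref <- if ("preferred" %in% names(records)) {
    v <- toupper(trimws(as.character(records$preferred)))
    v %in% c("1", "TRUE", "T", "YES", "Y")
  } else rep(FALSE, nrow(records))
  out <- data.frame(
    sample_name = as.character(records$sample_name),
    member_id = ids,
    plate = if ("plate" %in% names(records))
      as.character(records$plate) else NA_character_,
    well = if ("well" %in% names(records))
      as.character(records$well) else NA_character_,
    preferred = pref, stringsAsFactors = FALSE)
  # at most one preferred sample per member, over file + store
  cur <- db$tables$samples
  cur <- cur[!(cur$sample_name %in% out$sample_name), , drop = FALSE]
  all_pref <- c(out$member_id[out$preferred],
                cur$member_id[cur$preferred %in% TRUE])
  if (anyDuplicated(all_pref)) {
    stop("more than one preferred sample for member id(s): ",
         paste(unique(all_pref[duplicated(all_pref)]), collapse = ", "))
  }
  out
}

.gv_validators$traitmeta <- function(db, records) {
  gv_need_cols(records, c("name", "kind"), "trait metadata")
  kind <- as.character(records$kind)
  if (!all(kind %in% c("qualitative", "quantitative"))) {
    stop("trait kind must be 'qualitative' or 'quantitative'")
  }
  data.frame(name = as.character(records$name), kind = kind,
             stringsAsFactors = FALSE)
}

.gv_validators$traits <- function(db, records) {
  gv_need_cols(records, c("pedigree", "person", "trait", "value"), "traits")
  ids <- resolve_member(db, records$pedigree, records$person)
  tm <- db$tables$traitmeta
  tid <- tm$trait_id[match(as.character(records$trait), tm$name)]
  if (anyNA(tid)) {
    stop("unregistered trait(s): ",
         paste(unique(records$trait[is.na(tid)]), collapse = ", "))
  }
  value <- as.character(records$value)
  quant <- tm$kind[match(tid, tm$trait_id)] == "quantitative"
  badnum <- quant & is.na(suppressWarnings(as.numeric(value)))
  if (any(badnum)) {
    stop("non-numeric value(s) for quantitative trait: ",
         paste(utils::head(value[badnum], 5L), collapse = ", "))
  }
  data.frame(member_id = ids, trait_id = tid, value = value,
             stringsAsFactors = FALSE)
}

.gv_validators$markers <- function(db, records) {
  gv_need_cols(records, "name", "markers")
  nm <- trimws(as.character(records$name))
  if (any(nm == "" | is.na(nm))) stop("empty marker name(s)")
  al <- db$tables$marker_aliases
  clash <- nm %in% al$alias_name
  if (any(clash)) {
    stop("marker name(s) already in use as aliases: ",
         paste(utils::head(nm[clash], 5L), collapse = ", "))
  }
  data.frame(name = nm, stringsAsFactors = FALSE)
}

.gv_validators$marker_aliases <- function(db, records) {
  gv_need_cols(records, c("alias_name", "name"), "marker alias")
  alias <- trimws(as.character(records$alias_name))
  clash <- alias %in% db$tables$markers$name
  if (any(clash)) {
    stop("alias name(s) collide with canonical marker names: ",
         paste(utils::head(alias[clash], 5L), collapse = ", "))
  }
  ids <- resolve_marker(db, records$name)
  data.frame(alias_name = alias, marker_id = ids, stringsAsFactors = FALSE)
}

.gv_validators$marker_info <- function(db, records) {
  gv_need_cols(records, c("marker", "build", "chromosome", "bp"),
               "marker info")
  ids <- resolve_marker(db, records$marker)
  bp <- as.numeric(records$bp)
  if (any(is.na(bp) | bp < 1)) {
    stop("base-pair position(s) missing or < 1 for marker(s): ",
         paste(utils::head(records$marker[is.na(bp) | bp < 1], 5L),
               collapse = ", "))
  }
  numcol <- function(col) {
    if (col %in% names(records)) {
      suppressWarnings(as.numeric(records[[col]]))
    } else rep(NA_real_, nrow(records))
  }
  data.frame(marker_id = ids, build = as.character(records$build),
             chromosome = parse_chromosome(records$chromosome), bp = bp,
             avg_cm = numcol("avg_cm"), female_cm = numcol("female_cm"),
             male_cm = numcol("male_cm"), stringsAsFactors = FALSE)
}

.gv_validators$allele_map <- function(db, records) {
  gv_need_cols(records, c("experiment", "marker", "from_allele",
                          "to_allele"), "allele map")
  eid <- vapply(as.character(records$experiment), gv_experiment_id,
                integer(1), db = db)
  mid <- resolve_marker(db, records$marker)
  from <- as.character(records$from_allele)
  to <- as.character(records$to_allele)
  if (!all(from %in% GV_ALLELES) || !all(to %in% GV_ALLELES)) {
    stop("allele map uses code(s) outside the alphabet")
  }
  if (any(from == "0") || any(to == "0")) {
    stop("the missing code '0' may not be remapped")
  }
  out <- data.frame(experiment_id = eid, marker_id = mid,
                    from_allele = from, to_allele = to,
                    stringsAsFactors = FALSE)
  # mapping must stay injective per (experiment, marker) over file + store
  cur <- db$tables$allele_map
  cur <- cur[!(gv_key_string(cur, c("experiment_id", "marker_id",
                                    "from_allele")) %in%
                 gv_key_string(out, c("experiment_id", "marker_id",
                                      "from_allele"))), , drop = FALSE]
  pool <- rbind(out, cur[, names(out), drop = FALSE])
  tokey <- paste(pool$experiment_id, pool$marker_id, pool$to_allele,
                 sep = "\r")
  if (anyDuplicated(tokey)) {
    stop("allele map collapses two alleles onto one for an ",
         "(experiment, marker) pair")
  }
  out
}

# --- user-facing loader wrappers -------------------------------------------

gv_load_from <- function(db, table, x, mode, colmap, required,
                         optional = character(0)) {
  records <- gv_input(x, colmap, required, optional)
  gdb_load(db, table, records, mode)
}

#' Load pedigree members from a flat file or data frame
#'
#' Input columns: `pedigree`, `person`, and optionally `father`, `mother`
#' (names within the same pedigree; `"0"` or blank means unknown) and `sex`
#' (`1/2/0` or `M/F/U`).  See [gdb_load()] for the commit-flag protocol.
#'
#' @param db a `gdb` object.
#' @param x a data frame with the canonical columns, or a file path read
#'   through `colmap`.
#' @param mode load mode, see [gdb_load()].
#' @param colmap a [column_map()] describing the file layout.
#' @return A `load_report`.
#' @export
load_members <- function(db, x, mode = "dry_run", colmap = NULL) {
  gv_load_from(db, "members", x, mode, colmap, c("pedigree", "person"),
               c("father", "mother", "sex"))
}

#' @rdname load_members
#' @export
load_member_aliases <- function(db, x, mode = "dry_run", colmap = NULL) {
  gv_load_from(db, "member_aliases", x, mode, colmap,
               c("alias_pedigree", "alias_person", "pedigree", "person"))
}

#' @rdname load_members
#' @export
load_samples <- function(db, x, mode = "dry_run", colmap = NULL) {
  gv_load_from(db, "samples", x, mode, colmap,
               c("sample_name", "pedigree", "person"),
               c("plate", "well", "preferred"))
}

#' Load values of one trait for a set of members
#'
#' Registers the trait in the trait metadata table (with its kind, used to
#' validate values: quantitative traits must parse as numbers) and loads
#' per-member values.  Input columns: `pedigree`, `person`, `value`.
#'
#' @inheritParams load_members
#' @param trait trait name.
#' @param kind `"qualitative"` or `"quantitative"`.
#' @return A `load_report` for the trait values.
#' @export
load_trait <- function(db, x, trait, kind = "qualitative",
                       mode = "dry_run", colmap = NULL) {
  snap <- gdb_snapshot(db)
  meta_mode <- if (mode %in% c("commit", "commit_replace", "commit_update"))
    "commit" else "dry_run"
  r1 <- gdb_load(db, "traitmeta", data.frame(name = trait, kind = kind),
                 meta_mode)
  if (length(r1$errors)) {
    gdb_restore(db, snap)
    return(r1)
  }
  records <- gv_input(x, colmap, c("pedigree", "person", "value"))
  records$trait <- trait
  rep <- gdb_load(db, "traits", records, mode)
  if (length(rep$errors)) gdb_restore(db, snap)
  rep
}

#' @rdname load_members
#' @export
load_markers <- function(db, x, mode = "dry_run", colmap = NULL) {
  gv_load_from(db, "markers", x, mode, colmap, "name")
}

#' @rdname load_members
#' @export
load_marker_aliases <- function(db, x, mode = "dry_run", colmap = NULL) {
  gv_load_from(db, "marker_aliases", x, mode, colmap,
               c("alias_name", "name"))
}

#' Load marker map positions for one build
#'
#' Input columns: `marker`, `chromosome`, `bp`, and optionally `avg_cm`,
#' `female_cm`, `male_cm` (genetic positions in centimorgans).  Every
#' record is tagged with the map `build` it came from; the store may hold
#' several builds per marker, and selection always names the build to use.
#'
#' @inheritParams load_members
#' @param build map-build tag, e.g. `"hg19"`.
#' @return A `load_report`.
#' @export
load_marker_info <- function(db, x, build, mode = "dry_run",
                             colmap = NULL) {
  records <- gv_input(x, colmap, c("marker", "chromosome", "bp"),
                      c("avg_cm", "female_cm", "male_cm"))
  records$build <- build
  gdb_load(db, "marker_info", records, mode)
}

#' Load allele relabelling entries for an experiment
#'
#' Each entry remaps one allele code to another for one marker in one
#' experiment (e.g. `1 -> A`, `2 -> C` when a lab reported numeric labels).
#' Maps are applied at merge/export time and never rewrite stored data.
#' Input columns: `marker`, `from_allele`, `to_allele`.
#'
#' @inheritParams load_members
#' @param experiment experiment name the map applies to.
#' @return A `load_report`.
#' @export
load_allele_map <- function(db, x, experiment, mode = "dry_run",
                            colmap = NULL) {
  records <- gv_input(x, colmap, c("marker", "from_allele", "to_allele"))
  records$experiment <- experiment
  gdb_load(db, "allele_map", records, mode)
}
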