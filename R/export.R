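#' Describe an export run
#'
#' @param format `"columnar"` (delimited text), `"plink_ped"` (ped/map
#'   text), `"plink_bed"` (binary bed/bim/fam) or `"mega2"` (annotated
#'   pedigree/names/map text trio).
#' @param prefix output path prefix (files get format-specific suffixes).
#' @param delimiter delimiter for columnar output.
#' @param per_person_streaming process and write one person at a time
#'   (columnar and ped only); implies `collect_stats = FALSE` and keeps
#'   memory flat for very large extractions.
#' @param collect_stats gather allele/genotype frequency statistics.
#' @param phenotype_trait trait whose values fill the phenotype column of
#'   ped/fam output (`-9` when a member lacks it).
#' @return An object of class `export_spec`.
#' @export
export_spec <- function(format = c("columnar", "plink_ped", "plink_bed",
                                   "mega2"),
                        prefix = tempfile("genovault_export_"),
                        delimiter = c("tab", "comma", "whitespace"),
                        per_person_streaming = FALSE,
                        collect_stats = TRUE,
                        phenotype_trait = "affection") {
  format <- match.arg(format)
  if (per_person_streaming && collect_stats) {
    stop("per-person streaming implies collect_stats = FALSE")
  }
  if (per_person_streaming && !format %in% c("columnar", "plink_ped")) {
    stop("streaming is only available for columnar and ped output")
  }
  structure(list(format = format, prefix = prefix,
                 delimiter = match.arg(delimiter),
                 per_person_streaming = isTRUE(per_person_streaming),
                 collect_stats = isTRUE(collect_stats),
                 phenotype_trait = phenotype_trait),
            class = "export_spec")
}

#' Merge, filter and export genotypes
#'
#' The extraction pipeline: select members and markers, gather every
#' stored call for them from both the row store and the block store
#' (honouring active flags and preferred samples per the merge policy),
#' apply allele relabelling maps and exclusion masks, resolve each
#' (member, marker) to a single genotype by the trust rule, and write the
#' result in the requested dialect.  Conflicts are masked to the
#' dialect's missing code and logged; re-importing a PLINK export
#' reproduces the merged genotype matrix.
#'
#' @param db a `gdb` object.
#' @param selection a [selection_spec()].
#' @param policy a [merge_policy()].
#' @param spec an [export_spec()].
#' @return Invisibly, a list with `files` (paths written), `members`,
#'   `markers`, `matrix` (the merged call matrix, unless streaming),
#'   `conflicts` (the conflict log) and `freq` (a frequency report, when
#'   statistics were gathered).
#' @export
export_genotypes <- function(db, selection = selection_spec(),
                             policy = merge_policy(),
                             spec = export_spec()) {
  members <- select_members(db, selection)
  markers <- select_markers(db, selection)
  if (!nrow(markers) && spec$format != "columnar") {
    stop("empty marker selection")
  }
  if (spec$per_person_streaming) {
    return(gv_export_streaming(db, members, markers, selection, policy,
                               spec))
  }
  merged <- gv_merge_matrix(db, members, markers, selection, policy)
  mat <- merged$matrix
  conflicts <- merged$conflicts
  if (selection$drop_untyped_markers && ncol(mat)) {
    typed <- colSums(mat != GV_MISSING) > 0L
    mat <- mat[, typed, drop = FALSE]
    markers <- markers[typed, , drop = FALSE]
  }
  pheno <- gv_member_phenotype(db, members, spec$phenotype_trait)
  files <- switch(spec$format,
    columnar = gv_write_columnar(mat, members, markers, spec),
    plink_ped = gv_write_ped(mat, members, markers, pheno, spec),
    plink_bed = {
      mem <- members
      mem$phenotype <- pheno
      write_plink_bed(mat, mem, data.frame(
        marker = markers$name, chromosome = markers$chromosome,
        bp = markers$bp, avg_cm = markers$avg_cm,
        stringsAsFactors = FALSE), spec$prefix)
    },
    mega2 = gv_write_mega2(mat, members, markers, pheno, spec))
  freq <- if (spec$collect_stats) allele_frequencies(mat) else NULL
  invisible(list(files = files, members = members, markers = markers,
                 matrix = mat, conflicts = conflicts, freq = freq))
}

# Streaming export: one person's worth of data is merged, written and
# dropped at a time, so memory stays flat for very large extractions.
gv_export_streaming <- function(db, members, markers, selection, policy,
                                spec) {
  pheno <- gv_member_phenotype(db, members, spec$phenotype_trait)
  main <- paste0(spec$prefix,
                 if (spec$format == "columnar") ".txt" else ".ped")
  con <- file(main, "w")
  on.exit(close(con))
  if (spec$format == "columnar") {
    writeLines(paste(c("pedigree", "person", "father", "mother", "sex",
                       markers$name), collapse = gv_sep(spec$delimiter)),
               con)
  }
  conflicts <- list()
  for (i in seq_len(nrow(members))) {
    one <- members[i, , drop = FALSE]
    merged <- gv_merge_matrix(db, one, markers, selection, policy)
    if (nrow(merged$conflicts)) {
      conflicts[[length(conflicts) + 1L]] <- merged$conflicts
    }
    if (spec$format == "columnar") {
      writeLines(paste(c(one$pedigree, one$person,
                         ifelse(is.na(one$father), "0", one$father),
                         ifelse(is.na(one$mother), "0", one$mother),
                         gv_sex_code(one$sex), merged$matrix[1L, ]),
                       collapse = gv_sep(spec$delimiter)), con)
    } else {
      writeLines(gv_ped_lines(merged$matrix, one, pheno[i]), con)
    }
  }
  files <- main
  if (spec$format == "plink_ped") {
    map <- paste0(spec$prefix, ".map")
    utils::write.table(
      data.frame(markers$chromosome, markers$name,
                 ifelse(is.na(markers$avg_cm), 0, markers$avg_cm),
                 markers$bp),
      map, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    files <- c(main, map)
  }
  invisible(list(files = files, members = members, markers = markers,
                 matrix = NULL,
                 conflicts = if (length(conflicts))
                   do.call(rbind, conflicts) else
                     data.frame(pedigree = character(0),
                                person = character(0),
                                marker = character(0),
                                detail = character(0),
                                stringsAsFactors = FALSE),
                 freq = NULL))
}

# Build the merged member x marker call matrix plus the conflict log.
gv_merge_matrix <- function(db, members, markers, selection, policy) {
  eids <- if (!is.null(selection$experiments)) {
    vapply(selection$experiments, gv_experiment_id, integer(1), db = db)
  } else NULL
  tids <- if (!is.null(selection$technologies)) {
    vapply(selection$technologies, gv_technology_id, integer(1), db = db)
  } else NULL
  long <- gv_gather_calls(db, markers$marker_id, members$member_id,
                          eids, tids, policy$honor_active)
  if (policy$honor_preferred_sample) {
    long <- gv_prefer_samples(long, db$tables$samples)
  }
  long <- gv_apply_allele_maps(db, long)
  long <- apply_exclusions(long, markers, selection$exclusions, db)
  mat <- matrix(GV_MISSING, nrow(members), nrow(markers),
                dimnames = list(paste(members$pedigree, members$person,
                                      sep = ":"),
                                markers$name))
  if (!nrow(long)) {
    return(list(matrix = mat,
                conflicts = data.frame(pedigree = character(0),
                                       person = character(0),
                                       marker = character(0),
                                       detail = character(0),
                                       stringsAsFactors = FALSE)))
  }
  long$trust <- gv_effective_trust(db, long, policy)
  ex <- db$tables$experiments
  long$experiment <- ex$name[match(long$experiment_id, ex$experiment_id)]
  res <- gv_resolve_table(long)
  i <- match(res$member_id, members$member_id)
  j <- match(res$marker_id, markers$marker_id)
  ok <- !is.na(i) & !is.na(j)
  mat[cbind(i[ok], j[ok])] <- res$call[ok]
  cf <- res[res$conflict & ok, , drop = FALSE]
  conflicts <- data.frame(
    pedigree = members$pedigree[match(cf$member_id, members$member_id)],
    person = members$person[match(cf$member_id, members$member_id)],
    marker = markers$name[match(cf$marker_id, markers$marker_id)],
    detail = cf$detail, stringsAsFactors = FALSE)
  list(matrix = mat, conflicts = conflicts)
}

gv_member_phenotype <- function(db, members, trait) {
  if (is.null(trait)) return(rep(NA_character_, nrow(members)))
  tm <- db$tables$traitmeta
  tid <- tm$trait_id[match(trait, tm$name)]
  if (is.na(tid)) return(rep(NA_character_, nrow(members)))
  tr <- db$tables$traits
  tr <- tr[tr$trait_id == tid, , drop = FALSE]
  tr$value[match(members$member_id, tr$member_id)]
}

gv_write_columnar <- function(mat, members, markers, spec) {
  sep <- gv_sep(spec$delimiter)
  path <- paste0(spec$prefix, ".txt")
  d <- data.frame(pedigree = members$pedigree, person = members$person,
                  father = ifelse(is.na(members$father), "0",
                                  members$father),
                  mother = ifelse(is.na(members$mother), "0",
                                  members$mother),
                  sex = gv_sex_code(members$sex),
                  stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(mat))) d[[markers$name[j]]] <- mat[, j]
  utils::write.table(d, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

gv_ped_lines <- function(mat, members, pheno) {
  if (ncol(mat)) {
    a1 <- substr(mat, 1L, 1L)
    a2 <- substr(mat, 3L, 3L)
    geno <- matrix(paste(a1, a2), nrow = nrow(mat))
    geno_str <- apply(geno, 1L, paste, collapse = " ")
  } else {
    geno_str <- rep("", nrow(mat))
  }
  lead <- paste(members$pedigree, members$person,
                ifelse(is.na(members$father), "0", members$father),
                ifelse(is.na(members$mother), "0", members$mother),
                gv_sex_code(members$sex),
                ifelse(is.na(pheno), "-9", pheno))
  trimws(paste(lead, geno_str))
}

gv_write_ped <- function(mat, members, markers, pheno, spec) {
  ped <- paste0(spec$prefix, ".ped")
  map <- paste0(spec$prefix, ".map")
  writeLines(gv_ped_lines(mat, members, pheno), ped)
  utils::write.table(
    data.frame(markers$chromosome, markers$name,
               ifelse(is.na(markers$avg_cm), 0, markers$avg_cm),
               markers$bp),
    map, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  c(ped, map)
}

# Mega2-style annotated trio: a names file listing the traits and markers,
# a map file with genetic + physical positions, and a pedigree file in
# pre-makeped layout with one genotype (two alleles) per marker.
gv_write_mega2 <- function(mat, members, markers, pheno, spec) {
  names_f <- paste0(spec$prefix, ".names")
  map_f <- paste0(spec$prefix, ".map")
  ped_f <- paste0(spec$prefix, ".ped")
  writeLines(c("# genovault annotated fileset, version 1",
               "Type Name",
               paste("A", spec$phenotype_trait),
               paste("M", markers$name)), names_f)
  utils::write.table(
    data.frame(CHR = markers$chromosome, NAME = markers$name,
               AVG_CM = ifelse(is.na(markers$avg_cm), 0, markers$avg_cm),
               BP = markers$bp),
    map_f, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE)
  writeLines(gv_ped_lines(mat, members, pheno), ped_f)
  c(ped_f, names_f, map_f)
}

#' Allele and genotype frequencies of a merged call matrix
#'
#' Counts are taken over the exported matrix exactly as written, so the
#' report is consistent with the output files; frequencies are over
#' non-missing alleles/genotypes and sum to one per marker.
#'
#' @param mat character matrix of normalized calls (members x markers).
#' @return A list with data frames `alleles` (`marker`, `allele`,
#'   `count`, `freq`), `genotypes` (`marker`, `genotype`, `count`,
#'   `freq`) and `missing` (`marker`, `n_missing`).
#' @export
allele_frequencies <- function(mat) {
  mk <- colnames(mat)
  arows <- list()
  grows <- list()
  miss <- integer(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    g <- mat[, j]
    miss[j] <- sum(g == GV_MISSING)
    g <- g[g != GV_MISSING]
    if (length(g)) {
      gt <- table(g)
      grows[[length(grows) + 1L]] <- data.frame(
        marker = mk[j], genotype = names(gt), count = as.integer(gt),
        freq = as.integer(gt) / length(g), stringsAsFactors = FALSE)
      al <- c(substr(g, 1L, 1L), substr(g, 3L, 3L))
      at <- table(al)
      arows[[length(arows) + 1L]] <- data.frame(
        marker = mk[j], allele = names(at), count = as.integer(at),
        freq = as.integer(at) / length(al), stringsAsFactors = FALSE)
    }
  }
  empty <- function(col) data.frame(marker = character(0),
                                    x = character(0),
                                    count = integer(0),
                                    freq = numeric(0),
                                    stringsAsFactors = FALSE)
  list(alleles = if (length(arows)) do.call(rbind, arows) else {
         d <- empty(); names(d)[2] <- "allele"; d
       },
       genotypes = if (length(grows)) do.call(rbind, grows) else {
         d <- empty(); names(d)[2] <- "genotype"; d
       },
       missing = data.frame(marker = mk, n_missing = miss,
                            stringsAsFactors = FALSE))
}
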