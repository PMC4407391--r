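# Deterministic synthetic-data generators.  Every pipeline stage can be
# exercised from code alone: a full mini-study written in each import
# dialect, exact realizations of published-style agreement matrices, block
# layouts with prescribed per-chromosome occupancy, and the worked example
# used in the documentation.

#' Example agreement matrices from a duplicate-genotyping audit
#'
#' Two experiment pairs that repeatedly genotyped the same marker on
#' overlapping people.  `"same_labels"` is a pair sharing one labelling
#' scheme: 130 people were typed in the first experiment but not the
#' second, 2 only in the second, and 3 people are genuinely discordant
#' (1 at \[1/1, 1/2\], 2 at \[1/2, 1/1\]) — conflict resolution masks
#' exactly those 3.  `"relabelled"` is a pair where one lab reported
#' numeric allele labels (1/2) and the other letters (A/C): every doubly
#' typed member looks discordant until the allele map `1 -> A, 2 -> C` is
#' applied, after which all 1,053 agree.
#'
#' @param pair which example pair.
#' @return An integer matrix of joint genotype counts; rows are the first
#'   experiment's calls, columns the second's.
#' @export
duplicate_audit_counts <- function(pair = c("same_labels", "relabelled")) {
  pair <- match.arg(pair)
  if (pair == "same_labels") {
    m <- matrix(c(2,   1,   1,   0,
                  19,  194, 1,   0,
                  58,  2,   549, 0,
                  53,  0,   0,   534),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("0/0", "1/1", "1/2", "2/2"),
                                c("0/0", "1/1", "1/2", "2/2")))
  } else {
    m <- matrix(c(0, 0,   0,   0,
                  0, 190, 0,   0,
                  0, 0,   504, 0,
                  0, 0,   0,   359),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("0/0", "1/1", "1/2", "2/2"),
                                c("0/0", "A/A", "A/C", "C/C")))
  }
  storage.mode(m) <- "integer"
  m
}

#' Realize an agreement matrix as two experiments' call vectors
#'
#' Builds member-aligned call vectors whose cross-tabulation reproduces
#' the requested joint counts *exactly* (counts, not rates); members are
#' emitted cell by cell in row-major order, so the construction is
#' deterministic.
#'
#' @param counts matrix of non-negative joint counts with genotype labels
#'   as dimnames (first experiment on rows).
#' @return A list with `calls_a`, `calls_b` (character vectors of length
#'   `sum(counts)`) and `member` (1..n identifiers).
#' @export
make_agreement_fixture <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  ra <- rownames(counts)
  cb <- colnames(counts)
  if (is.null(ra) || is.null(cb)) {
    stop("counts needs genotype labels as dimnames")
  }
  calls_a <- character(0)
  calls_b <- character(0)
  for (i in seq_along(ra)) {
    for (j in seq_along(cb)) {
      k <- counts[i, j]
      if (k > 0) {
        calls_a <- c(calls_a, rep(ra[[i]], k))
        calls_b <- c(calls_b, rep(cb[[j]], k))
      }
    }
  }
  list(calls_a = calls_a, calls_b = calls_b,
       member = seq_along(calls_a))
}

#' Per-chromosome block occupancy of the exome-chip subset example
#'
#' The per-chromosome genotype-block counts of a 25,143-marker exome-chip
#' subset stored at 500 genotypes per block: chromosome 1 occupies 5
#' blocks; 2, 6 and 11 occupy 4 each; 3, 4, 5, 7, 9, 12, 16, 17 and 19
#' occupy 3 each; 8, 10, 14, 15, 20, 22 and 23 occupy 2 each; and 13, 18,
#' 21, 24 and 26 occupy 1 each — 63 blocks per sample in total.
#'
#' @return Named integer vector, chromosome -> block count.
#' @export
exome_chip_block_occupancy <- function() {
  c(`1` = 5L, `2` = 4L, `3` = 3L, `4` = 3L, `5` = 3L, `6` = 4L, `7` = 3L,
    `8` = 2L, `9` = 3L, `10` = 2L, `11` = 4L, `12` = 3L, `13` = 1L,
    `14` = 2L, `15` = 2L, `16` = 3L, `17` = 3L, `18` = 1L, `19` = 3L,
    `20` = 2L, `21` = 1L, `22` = 2L, `23` = 2L, `24` = 1L, `26` = 1L)
}

#' Build a marker map realizing a prescribed block occupancy
#'
#' Chooses per-chromosome marker counts so that a chromosome requested to
#' occupy `k` blocks gets between `(k-1)*B + 1` and `k*B` markers, and the
#' total equals `n_markers` (minimal feasible total when omitted); errors
#' when the total is infeasible.  Marker names and base-pair positions are
#' deterministic.
#'
#' @param block_counts named integer vector, chromosome -> block count.
#' @param block_size genotypes per block.
#' @param n_markers total marker count, or `NULL` for the minimum.
#' @return A data frame with `marker`, `chromosome`, `bp` suitable as a
#'   mapping input for the genome-wide importers.
#' @export
make_layout_fixture <- function(block_counts, block_size = 500L,
                                n_markers = NULL) {
  if (is.null(names(block_counts))) {
    stop("block_counts must be named by chromosome")
  }
  k <- as.integer(block_counts)
  if (any(k < 1L)) stop("block counts must be positive")
  B <- as.integer(block_size)
  lo <- (k - 1L) * B + 1L
  hi <- k * B
  total_lo <- sum(lo)
  total_hi <- sum(hi)
  if (is.null(n_markers)) n_markers <- total_lo
  if (n_markers < total_lo || n_markers > total_hi) {
    stop("requested ", n_markers, " markers is infeasible for this ",
         "occupancy (needs ", total_lo, "..", total_hi, ")")
  }
  counts <- lo
  extra <- n_markers - total_lo
  for (i in seq_along(counts)) {
    add <- min(extra, hi[[i]] - counts[[i]])
    counts[[i]] <- counts[[i]] + add
    extra <- extra - add
    if (extra == 0L) break
  }
  chrom <- as.integer(rep(names(block_counts), counts))
  within <- sequence(counts)
  data.frame(
    marker = sprintf("snp%02d_%05d", chrom, within),
    chromosome = chrom,
    bp = within * 1000,
    stringsAsFactors = FALSE)
}

#' Deterministic per-sample genotype generator over a marker map
#'
#' Draws, once, two alleles and an allele frequency per marker (uniform
#' frequencies, Hardy-Weinberg genotype draws), then hands out one
#' reproducible call set per sample index.  The same seed yields
#' byte-identical output; missing calls are `0/0` at the given rate.
#'
#' @param map marker map data frame (needs a `marker` column).
#' @param n_samples number of samples the generator serves.
#' @param seed integer seed driving all randomness.
#' @param missing_rate per-call missingness probability.
#' @return A function of the sample index returning a data frame with
#'   `marker`, `allele1`, `allele2`.
#' @export
sample_call_generator <- function(map, n_samples, seed = 1L,
                                  missing_rate = 0.02) {
  m <- nrow(map)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  shift <- sample.int(3L, m, replace = TRUE)
  alt <- bases[(match(ref, bases) + shift - 1L) %% 4L + 1L]
  p <- stats::runif(m, 0.05, 0.95)
  seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
  marker <- map$marker
  function(i) {
    set.seed(seeds[[i]])
    a1 <- ifelse(stats::runif(m) < p, ref, alt)
    a2 <- ifelse(stats::runif(m) < p, ref, alt)
    if (missing_rate > 0) {
      miss <- stats::runif(m) < missing_rate
      a1[miss] <- "0"
      a2[miss] <- "0"
    }
    data.frame(marker = marker, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  }
}

#' Generate a cohort of unrelated members with one sample each
#'
#' @param n number of members/samples.
#' @param prefix name prefix.
#' @return A list with `members` and `samples` data frames ready for
#'   [load_members()] / [load_samples()].
#' @export
make_sample_cohort <- function(n, prefix = "S") {
  ped <- sprintf("%sPED%05d", prefix, seq_len(n))
  person <- rep("P1", n)
  list(members = data.frame(pedigree = ped, person = person,
                            sex = "U", stringsAsFactors = FALSE),
       samples = data.frame(sample_name = sprintf("%s%05d", prefix,
                                                  seq_len(n)),
                            pedigree = ped, person = person,
                            stringsAsFactors = FALSE))
}

#' Generate a complete synthetic study on disk
#'
#' Writes a mutually consistent fileset — members (nuclear pedigrees with
#' parent links), one sample per member, a qualitative affection trait, a
#' marker map, per-sample genotype files, a wide multi-sample genotype
#' file and a targeted (long-format) genotype file — all realizing the
#' same underlying call matrix, so any import dialect loads end-to-end
#' with zero errors and cross-dialect equivalence can be checked.  All
#' randomness is driven by `seed`; the same seed reproduces the files
#' byte for byte.
#'
#' @param dir output directory (created).
#' @param n_pedigrees number of nuclear families (2 parents + children).
#' @param n_children children per family.
#' @param markers_per_chromosome named integer vector, chromosome ->
#'   marker count.
#' @param missing_rate per-call missingness probability (0 gives a fully
#'   typed matrix, 1 an all-missing one).
#' @param seed integer seed.
#' @return A list with file paths (`members`, `samples`, `traits`, `map`,
#'   `per_sample` (a named list), `multi_sample`, `targeted`), the
#'   `truth` call matrix (samples x markers) and the member/sample
#'   tables.
#' @export
make_study <- function(dir, n_pedigrees = 2L, n_children = 2L,
                       markers_per_chromosome = c(`1` = 6L, `2` = 4L),
                       missing_rate = 0.05, seed = 1L) {
  if (n_pedigrees < 1L || n_children < 0L) {
    stop("impossible pedigree specification")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  members <- do.call(rbind, lapply(seq_len(n_pedigrees), function(p) {
    ped <- sprintf("F%02d", p)
    kids <- if (n_children > 0) sprintf("P%d", 2L + seq_len(n_children))
      else character(0)
    data.frame(
      pedigree = ped,
      person = c("P1", "P2", kids),
      father = c("0", "0", rep("P1", n_children)),
      mother = c("0", "0", rep("P2", n_children)),
      sex = c("1", "2", sample(c("1", "2"), n_children, replace = TRUE)),
      stringsAsFactors = FALSE)
  }))
  samples <- data.frame(
    sample_name = paste0("S_", members$pedigree, "_", members$person),
    pedigree = members$pedigree, person = members$person,
    stringsAsFactors = FALSE)
  traits <- data.frame(pedigree = members$pedigree,
                       person = members$person,
                       value = sample(c("1", "2"), nrow(members),
                                      replace = TRUE),
                       stringsAsFactors = FALSE)
  chrom <- as.integer(rep(names(markers_per_chromosome),
                          markers_per_chromosome))
  within <- sequence(as.integer(markers_per_chromosome))
  map <- data.frame(marker = sprintf("mk%02d_%03d", chrom, within),
                    chromosome = chrom, bp = within * 1e6,
                    avg_cm = within * 1.0, stringsAsFactors = FALSE)
  gen <- sample_call_generator(map, nrow(samples),
                               seed = seed + 104729L,
                               missing_rate = missing_rate)
  truth <- matrix(GV_MISSING, nrow(samples), nrow(map),
                  dimnames = list(samples$sample_name, map$marker))
  per_sample <- list()
  psdir <- file.path(dir, "per_sample")
  dir.create(psdir, showWarnings = FALSE)
  for (i in seq_len(nrow(samples))) {
    calls <- gen(i)
    truth[i, ] <- normalize_call(calls$allele1, calls$allele2)
    f <- file.path(psdir, paste0(samples$sample_name[i], ".tsv"))
    data.table::fwrite(calls, f, sep = "\t")
    per_sample[[samples$sample_name[i]]] <- f
  }
  wide <- data.frame(marker = map$marker, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(samples))) {
    wide[[samples$sample_name[i]]] <- truth[i, ]
  }
  targeted <- data.frame(
    pedigree = rep(members$pedigree, times = nrow(map)),
    person = rep(members$person, times = nrow(map)),
    marker = rep(map$marker, each = nrow(members)),
    allele1 = substr(c(truth), 1L, 1L),
    allele2 = substr(c(truth), 3L, 3L),
    stringsAsFactors = FALSE)
  paths <- list(members = file.path(dir, "members.tsv"),
                samples = file.path(dir, "samples.tsv"),
                traits = file.path(dir, "traits.tsv"),
                map = file.path(dir, "map.tsv"),
                multi_sample = file.path(dir, "multi_sample.tsv"),
                targeted = file.path(dir, "targeted.tsv"))
  data.table::fwrite(members, paths$members, sep = "\t")
  data.table::fwrite(samples, paths$samples, sep = "\t")
  data.table::fwrite(traits, paths$traits, sep = "\t")
  data.table::fwrite(map, paths$map, sep = "\t")
  data.table::fwrite(wide, paths$multi_sample, sep = "\t")
  data.table::fwrite(targeted, paths$targeted, sep = "\t")
  c(paths, list(per_sample = per_sample, truth = truth,
                members_table = members, samples_table = samples,
                map_table = map))
}

#' Database fixture for the marker look-up worked example
#'
#' Builds a populated database illustrating the retrieval paths: one
#' member with one sample, typed by a targeted experiment (`Exp D`, row
#' store) and a genome-wide experiment (`Exp F`, block store).
#' Chromosome 1 carries `rs123401` (outside the 10-20 Mb window) and
#' `rs123451`/`rs123452` (inside it); chromosome 2 was loaded with 499
#' filler markers plus `rs456784` in the final slot of its block, and
#' `rs456784` has since moved to chromosome 3 in the current map build
#' and gained the alias `rs34567`.  The two experiments agree at
#' `rs123401` (one is missing) and `rs123452`, and disagree at
#' `rs123451` (`1/2` vs `G/T`).
#'
#' @param build map-build tag used for the current positions.
#' @return A list with the populated `db`, the `layout` name, the member
#'   and experiment names, and `expected` (the merged calls of the three
#'   chromosome-1 markers).
#' @export
make_marker_lookup_fixture <- function(build = "b37") {
  db <- gdb_create()
  r <- load_members(db, data.frame(pedigree = "F1", person = "P1",
                                   sex = "1"), mode = "commit")
  stopifnot(r$committed)
  r <- load_samples(db, data.frame(sample_name = "S1", pedigree = "F1",
                                   person = "P1"), mode = "commit")
  stopifnot(r$committed)
  gdb_create_experiment(db, "Exp D", "TaqMan")
  gdb_create_experiment(db, "Exp F", "Illumina")

  fill1 <- sprintf("c1f%03d", 1:4)
  fill2 <- sprintf("c2f%03d", 1:499)
  map <- data.frame(
    marker = c("rs123401", fill1, "rs123451", "rs123452",
               fill2, "rs456784"),
    chromosome = c(rep(1L, 7L), rep(2L, 500L)),
    bp = c(5e6, 6e6, 6.5e6, 7e6, 8e6, 12e6, 15e6,
           (1:499) * 1e5, 6e7),
    stringsAsFactors = FALSE)
  calls <- data.frame(
    marker = map$marker,
    genotype = c("A/C", rep("0/0", 4L), "G/T", "A/C",
                 rep("0/0", 499L), "G/T"),
    stringsAsFactors = FALSE)
  r <- import_per_sample_files(db, map, list(S1 = calls), "Exp F",
                               layout = "chip1", block_size = 500L,
                               build = build, mode = "commit")
  stopifnot(r$committed, length(r$errors) == 0L)

  # current build: rs456784 has moved to chromosome 3
  r <- gdb_load(db, "marker_info",
                data.frame(marker = "rs456784", build = build,
                           chromosome = 3L, bp = 3e7,
                           stringsAsFactors = FALSE), "commit_update")
  stopifnot(r$committed)
  r <- load_marker_aliases(db, data.frame(alias_name = "rs34567",
                                          name = "rs456784"),
                           mode = "commit")
  stopifnot(r$committed)

  r <- import_targeted_genotypes(
    db, data.frame(pedigree = "F1", person = "P1",
                   marker = c("rs123401", "rs123451", "rs123452"),
                   genotype = c("0/0", "1/2", "A/C"),
                   stringsAsFactors = FALSE),
    experiment = "Exp D", technology = "TaqMan", mode = "commit",
    store_missing = TRUE)
  stopifnot(r$committed, length(r$errors) == 0L)

  list(db = db, layout = "chip1", member = c("F1", "P1"),
       experiments = c("Exp D", "Exp F"), build = build,
       expected = c(rs123401 = "A/C", rs123451 = GV_MISSING,
                    rs123452 = "A/C"))
}
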