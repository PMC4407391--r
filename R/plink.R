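# PLINK 1 fileset codecs.  The binary .bed layout (v1): three magic bytes
# 0x6C 0x1B 0x01 (the third marks SNP-major order), then for each variant
# ceiling(n/4) bytes, two bits per individual starting at the low bits:
# 00 = homozygous A1, 01 = missing, 10 = heterozygous, 11 = homozygous A2.

gv_bed_magic <- as.raw(c(0x6c, 0x1b))

# 256 x 4 lookup: byte value -> the four 2-bit codes it packs.
gv_bed_lut <- local({
  b <- 0:255
  cbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
})

#' Read a PLINK 1 binary fileset
#'
#' @param bed,bim,fam file paths.
#' @return A list with `calls` (character matrix of normalized calls,
#'   samples in rows named `FID:IID`, markers in columns), `bim` (data
#'   frame: `chromosome`, `marker`, `cm`, `bp`, `a1`, `a2`) and `fam`
#'   (data frame: `pedigree`, `person`, `father`, `mother`, `sex`,
#'   `phenotype`).
#' @export
read_plink_bed <- function(bed, bim, fam) {
  bimd <- utils::read.table(bim, header = FALSE, colClasses = "character")
  names(bimd) <- c("chromosome", "marker", "cm", "bp", "a1", "a2")
  famd <- utils::read.table(fam, header = FALSE, colClasses = "character")
  names(famd) <- c("pedigree", "person", "father", "mother", "sex",
                   "phenotype")
  n <- nrow(famd)
  m <- nrow(bimd)
  bpm <- ceiling(n / 4)
  raw <- readBin(bed, what = "raw", n = 3L + bpm * m)
  if (length(raw) < 3L || !identical(raw[1:2], gv_bed_magic)) {
    stop("not a PLINK 1 binary file (bad magic bytes): ", bed)
  }
  if (raw[3L] == as.raw(0x00)) {
    stop("individual-major .bed files are not supported")
  }
  if (raw[3L] != as.raw(0x01)) stop("unrecognized .bed mode byte")
  if (length(raw) != 3L + bpm * m) {
    stop(".bed size does not match ", n, " individuals x ", m, " variants")
  }
  body <- as.integer(raw[-(1:3)]) + 1L
  calls <- matrix(NA_character_, n, m,
                  dimnames = list(paste(famd$pedigree, famd$person,
                                        sep = ":"),
                                  bimd$marker))
  safe_call <- function(x1, x2) {
    if (xor(x1 == "0", x2 == "0")) NA_character_ else normalize_call(x1, x2)
  }
  for (j in seq_len(m)) {
    bytes <- body[((j - 1L) * bpm + 1L):(j * bpm)]
    codes <- as.vector(t(gv_bed_lut[bytes, , drop = FALSE]))[seq_len(n)]
    g <- c(safe_call(bimd$a1[j], bimd$a1[j]), GV_MISSING,
           safe_call(bimd$a1[j], bimd$a2[j]),
           safe_call(bimd$a2[j], bimd$a2[j]))
    if (anyNA(g[unique(codes) + 1L])) {
      stop("variant ", bimd$marker[j],
           " uses the null allele '0' in a called genotype")
    }
    calls[, j] <- g[codes + 1L]
  }
  list(calls = calls, bim = bimd, fam = famd)
}

#' Write a genotype matrix as a PLINK 1 binary fileset
#'
#' Markers must be biallelic-or-missing after merging; a marker with more
#' than two distinct alleles is an error naming it.  A1 is the minor
#' allele by frequency (ties broken by allele-code order) and A2 the
#' major; an all-missing marker gets `0 0`.
#'
#' @param calls character matrix of normalized calls, samples in rows,
#'   markers in columns.
#' @param members data frame with `pedigree`, `person`, `father`,
#'   `mother`, `sex` (and optionally `phenotype`), one row per sample row.
#' @param markers data frame with `marker`, `chromosome`, `bp` and
#'   optionally `avg_cm`, one row per call column.
#' @param prefix output path prefix; writes `<prefix>.bed/.bim/.fam`.
#' @return The three file paths, invisibly.
#' @export
write_plink_bed <- function(calls, members, markers, prefix) {
  n <- nrow(calls)
  m <- ncol(calls)
  stopifnot(nrow(members) == n, nrow(markers) == m)
  fam <- data.frame(
    members$pedigree, members$person,
    ifelse(is.na(members$father), "0", members$father),
    ifelse(is.na(members$mother), "0", members$mother),
    gv_sex_code(members$sex),
    if ("phenotype" %in% names(members))
      ifelse(is.na(members$phenotype), "-9", members$phenotype) else "-9")
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  a12 <- gv_marker_alleles(calls, markers$marker)
  cm <- if ("avg_cm" %in% names(markers))
    ifelse(is.na(markers$avg_cm), 0, markers$avg_cm) else 0
  bim <- data.frame(markers$chromosome, markers$marker, cm, markers$bp,
                    a12$a1, a12$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  bpm <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(gv_bed_magic, as.raw(0x01)), con)
  pad <- 4L * bpm - n
  for (j in seq_len(m)) {
    g <- calls[, j]
    code <- integer(n)
    code[g == GV_MISSING] <- 1L
    hom1 <- normalize_call(a12$a1[j], a12$a1[j])
    het <- if (a12$a2[j] != "0" && a12$a1[j] != "0")
      normalize_call(a12$a1[j], a12$a2[j]) else NA_character_
    hom2 <- if (a12$a2[j] != "0")
      normalize_call(a12$a2[j], a12$a2[j]) else NA_character_
    code[!is.na(het) & g == het] <- 2L
    code[!is.na(hom2) & g == hom2] <- 3L
    # hom1 stays 0
    codes <- c(code, rep(0L, pad))   # trailing pad bits are zero
    q <- matrix(codes, nrow = 4L)
    writeBin(as.raw(q[1L, ] + 4L * q[2L, ] + 16L * q[3L, ] +
                      64L * q[4L, ]), con)
  }
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

# Per-marker A1/A2 assignment: A1 = minor allele by count, ties broken by
# allele-code order; monomorphic markers get A2 = the one allele, A1 = "0".
gv_marker_alleles <- function(calls, marker_names) {
  m <- ncol(calls)
  a1 <- character(m)
  a2 <- character(m)
  for (j in seq_len(m)) {
    g <- calls[, j]
    al <- c(substr(g, 1L, 1L), substr(g, 3L, 3L))
    al <- al[al != "0"]
    tab <- table(al)
    alleles <- names(tab)
    if (length(alleles) > 2L) {
      stop("marker ", marker_names[j], " has more than two alleles (",
           paste(alleles, collapse = ","), "); cannot be written as PLINK")
    }
    if (length(alleles) == 0L) {
      a1[j] <- "0"; a2[j] <- "0"
    } else if (length(alleles) == 1L) {
      a1[j] <- "0"; a2[j] <- alleles
    } else {
      ord <- order(tab, gv_allele_rank(alleles))
      a1[j] <- alleles[ord[1L]]
      a2[j] <- alleles[ord[2L]]
    }
  }
  list(a1 = a1, a2 = a2)
}

#' Read a PLINK ped/map text fileset into long genotype records
#'
#' @param ped,map file paths.
#' @return A list with `members` (pedigree columns of the ped file),
#'   `map` (data frame `chromosome`, `marker`, `cm`, `bp`) and `calls`
#'   (long data frame: `pedigree`, `person`, `marker`, `allele1`,
#'   `allele2`).
#' @export
read_plink_ped <- function(ped, map) {
  mapd <- utils::read.table(map, header = FALSE, colClasses = "character")
  names(mapd) <- c("chromosome", "marker", "cm", "bp")
  pedd <- utils::read.table(ped, header = FALSE, colClasses = "character")
  m <- nrow(mapd)
  if (ncol(pedd) != 6L + 2L * m) {
    stop("ped file has ", ncol(pedd), " columns; expected ", 6L + 2L * m)
  }
  members <- pedd[, 1:6]
  names(members) <- c("pedigree", "person", "father", "mother", "sex",
                      "phenotype")
  a1 <- as.matrix(pedd[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(pedd[, 6L + 2L * seq_len(m), drop = FALSE])
  calls <- data.frame(
    pedigree = rep(members$pedigree, times = m),
    person = rep(members$person, times = m),
    marker = rep(mapd$marker, each = nrow(members)),
    allele1 = as.vector(a1), allele2 = as.vector(a2),
    stringsAsFactors = FALSE)
  list(members = members, map = mapd, calls = calls)
}
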