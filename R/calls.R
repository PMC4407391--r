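# Allele alphabet, in normalization (byte-code) order: digits before letters.
GV_ALLELES <- c("0", as.character(1:9), "A", "C", "G", "T")

#' The missing genotype code
#'
#' `"0/0"` denotes an unknown genotype throughout the package: untyped cells,
#' padding slots in genotype blocks, and genotypes masked by conflict
#' resolution all carry this value.
#' @export
GV_MISSING <- "0/0"

gv_allele_rank <- function(a) match(a, GV_ALLELES)

#' Normalize a genotype call to an unordered allele pair
#'
#' Genotypes are stored as unordered pairs of single-character allele codes
#' over the alphabet `{0, 1-9, A, C, G, T}`, written `"a1/a2"` with the
#' alleles in fixed (digits-before-letters) order, so that `"C","A"` and
#' `"A","C"` compare equal.  `"0"` is the missing code and may only appear as
#' the full pair `0/0`; a half-missing genotype (exactly one allele `"0"`)
#' signals malformed input and is rejected.  Normalization is idempotent.
#'
#' @param a1,a2 character vectors of single allele codes (recycled to a
#'   common length).
#' @return A character vector of normalized calls such as `"A/C"` or `"0/0"`.
#' @examples
#' normalize_call("C", "A")   # "A/C"
#' normalize_call("0", "0")   # "0/0"
#' normalize_call(c("G", "2"), c("T", "1"))
#' @export
normalize_call <- function(a1, a2) {
  a1 <- as.character(a1)
  a2 <- as.character(a2)
  if (!length(a1) && !length(a2)) return(character(0))
  n <- max(length(a1), length(a2))
  a1 <- rep_len(a1, n)
  a2 <- rep_len(a2, n)
  r1 <- gv_allele_rank(a1)
  r2 <- gv_allele_rank(a2)
  bad <- is.na(r1) | is.na(r2)
  if (any(bad)) {
    stop("allele code(s) outside the {0,1-9,A,C,G,T} alphabet: ",
         paste(unique(c(a1[bad & is.na(r1)], a2[bad & is.na(r2)])),
               collapse = ", "))
  }
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    stop("half-missing genotype (exactly one allele '0') in ",
         sum(half), " call(s); refusing to guess")
  }
  swap <- r1 > r2
  lo <- ifelse(swap, a2, a1)
  hi <- ifelse(swap, a1, a2)
  paste0(lo, "/", hi)
}

#' Split normalized calls into their two alleles
#'
#' @param calls character vector of `"a1/a2"` calls.
#' @return A two-column character matrix (`a1`, `a2`).
#' @export
call_alleles <- function(calls) {
  parts <- strsplit(as.character(calls), "/", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != 2L)) {
    stop("malformed call(s): ", paste(utils::head(calls[lens != 2L], 5L),
                                      collapse = ", "))
  }
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("a1", "a2")
  m
}

# Parse a column of genotype strings ("A/C", "A C", "AC") into two alleles.
gv_split_genotype <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("[/ ,:]", "", x)
  bad <- nchar(x) != 2L
  if (any(bad)) {
    stop("genotype field(s) not reducible to two allele codes: ",
         paste(utils::head(unique(x[bad]), 5L), collapse = ", "))
  }
  list(a1 = substr(x, 1L, 1L), a2 = substr(x, 2L, 2L))
}

# Order genotype call labels: 0/0 first, then by allele rank.
gv_sort_calls <- function(calls) {
  calls <- unique(as.character(calls))
  al <- call_alleles(calls)
  ord <- order(gv_allele_rank(al[, 1L]), gv_allele_rank(al[, 2L]))
  calls <- calls[ord]
  c(intersect(GV_MISSING, calls), setdiff(calls, GV_MISSING))
}

#' Parse sex codes
#'
#' Accepts the PLINK-style numeric codes `1` (male), `2` (female), `0`
#' (unknown) as well as `M`/`F`/`U` (case-insensitive) and the full words;
#' empty or `NA` input maps to `"unknown"`.
#'
#' @param x character or numeric vector of sex codes.
#' @return Character vector over `c("male", "female", "unknown")`.
#' @export
parse_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("1", "M", "MALE")] <- "male"
  out[x %in% c("2", "F", "FEMALE")] <- "female"
  known <- x %in% c("1", "2", "0", "M", "F", "U", "MALE", "FEMALE",
                    "UNKNOWN", "", "NA")
  known <- known | is.na(x)
  if (!all(known)) {
    stop("unrecognized sex code(s): ",
         paste(unique(x[!known]), collapse = ", "))
  }
  out
}

# Sex back to PLINK numeric coding.
gv_sex_code <- function(sex) {
  c(male = 1L, female = 2L, unknown = 0L)[sex]
}

#' Parse chromosome labels
#'
#' Chromosomes are stored as integers 1-26 with 23=X, 24=Y, 25=XY (the
#' pseudoautosomal region) and 26=MT, matching common linkage-format
#' conventions.  Accepts integer labels and the X/Y/XY/MT strings.
#'
#' @param x vector of chromosome labels.
#' @return Integer vector in 1..26.
#' @export
parse_chromosome <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x == "X"] <- "23"
  x[x == "Y"] <- "24"
  x[x == "XY"] <- "25"
  x[x %in% c("MT", "M")] <- "26"
  out <- suppressWarnings(as.integer(x))
  bad <- is.na(out) | out < 1L | out > 26L
  if (any(bad)) {
    stop("unrecognized chromosome label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  out
}
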