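# Small in-code fixtures shared across the suite.

# Two nuclear pedigrees, one sample per member, an affection trait, five
# registered markers with build "1" map info, and two experiments.
tiny_db <- function(trust = c(expA = 0L, expB = 0L)) {
  db <- gdb_create()
  members <- data.frame(
    pedigree = c("F1", "F1", "F1", "F1", "F2", "F2", "F2"),
    person = c("P1", "P2", "P3", "P4", "P1", "P2", "P3"),
    father = c("0", "0", "P1", "P1", "0", "0", "P1"),
    mother = c("0", "0", "P2", "P2", "0", "0", "P2"),
    sex = c("1", "2", "1", "2", "1", "2", "2"),
    stringsAsFactors = FALSE)
  stopifnot(load_members(db, members, mode = "commit")$committed)
  samples <- data.frame(
    sample_name = paste0("S_", members$pedigree, "_", members$person),
    pedigree = members$pedigree, person = members$person,
    stringsAsFactors = FALSE)
  stopifnot(load_samples(db, samples, mode = "commit")$committed)
  aff <- data.frame(pedigree = members$pedigree, person = members$person,
                    value = c("2", "1", "2", "1", "1", "1", "2"),
                    stringsAsFactors = FALSE)
  stopifnot(load_trait(db, aff, "affection", "qualitative",
                       mode = "commit")$committed)
  mk <- data.frame(name = paste0("rs", 1:5), stringsAsFactors = FALSE)
  stopifnot(load_markers(db, mk, mode = "commit")$committed)
  info <- data.frame(marker = mk$name,
                     chromosome = c(1, 1, 1, 2, 2),
                     bp = c(100, 200, 300, 100, 250),
                     avg_cm = c(0.1, 0.2, NA, 0.1, 0.3),
                     stringsAsFactors = FALSE)
  stopifnot(load_marker_info(db, info, build = "1",
                             mode = "commit")$committed)
  for (e in names(trust)) {
    gdb_create_experiment(db, e, "tech1", trust = trust[[e]])
  }
  db
}

# Random normalized calls over a given allele set.
random_calls <- function(n, alleles = c("0", "A", "C", "G", "T")) {
  a1 <- sample(alleles, n, replace = TRUE)
  a2 <- sample(alleles, n, replace = TRUE)
  a2[xor(a1 == "0", a2 == "0")] <- "0"
  a1[a2 == "0"] <- "0"
  normalize_call(a1, a2)
}

expect_tables_equal <- function(db, snapshot) {
  expect_identical(gdb_tables(db), snapshot$tables)
}
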