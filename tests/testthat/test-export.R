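study_db <- function(seed = 33, missing_rate = 0.1, block_size = 3,
                     markers = c(`1` = 4, `2` = 3)) {
  dir <- tempfile("study_")
  st <- make_study(dir, n_pedigrees = 2, n_children = 1,
                   markers_per_chromosome = markers,
                   missing_rate = missing_rate, seed = seed)
  db <- gdb_create()
  stopifnot(load_members(db, st$members, mode = "commit")$committed)
  stopifnot(load_samples(db, st$samples, mode = "commit")$committed)
  gdb_create_experiment(db, "gw", "chip")
  r <- import_per_sample_files(db, st$map, st$per_sample, "gw",
                               layout = "chip", block_size = block_size,
                               build = "1", mode = "commit")
  stopifnot(r$committed)
  list(db = db, st = st)
}

test_that("columnar, ped and bed exports decode to the same matrix", {
  x <- study_db()
  sel <- selection_spec(build = "1")
  col <- export_genotypes(x$db, sel,
                          spec = export_spec(prefix = tempfile()))
  ped <- export_genotypes(x$db, sel,
                          spec = export_spec(format = "plink_ped",
                                             prefix = tempfile()))
  bed <- export_genotypes(x$db, sel,
                          spec = export_spec(format = "plink_bed",
                                             prefix = tempfile()))
  expect_identical(col$matrix, ped$matrix)
  expect_identical(col$matrix, bed$matrix)
  # columnar file content matches the matrix
  d <- utils::read.delim(col$files[1], colClasses = "character",
                         check.names = FALSE)
  expect_identical(unname(as.matrix(d[, colnames(col$matrix)])),
                   unname(col$matrix))
  # ped text decodes back to the same calls
  back <- read_plink_ped(ped$files[1], ped$files[2])
  m <- matrix(normalize_call(
    ifelse(back$calls$allele1 == "0", "0", back$calls$allele1),
    ifelse(back$calls$allele1 == "0", "0", back$calls$allele2)),
    nrow = nrow(col$matrix),
    dimnames = list(paste(back$members$pedigree, back$members$person,
                          sep = ":"), unique(back$calls$marker)))
  expect_identical(m[rownames(col$matrix), colnames(col$matrix)],
                   col$matrix)
  # binary decodes back to the same calls
  px <- read_plink_bed(bed$files[1], bed$files[2], bed$files[3])
  expect_identical(px$calls[rownames(col$matrix), colnames(col$matrix)],
                   col$matrix)
  # mega2-style trio carries the same pedigree lines as ped
  mg <- export_genotypes(x$db, sel,
                         spec = export_spec(format = "mega2",
                                            prefix = tempfile()))
  expect_identical(readLines(mg$files[1]), readLines(ped$files[1]))
  expect_match(readLines(mg$files[2])[1], "version")
})

test_that("PLINK binary write/read round-trips random biallelic matrices", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(1:9, 1)
    m <- sample(1:6, 1)
    mat <- matrix("0/0", n, m,
                  dimnames = list(paste0("F", 1:n, ":P1"),
                                  paste0("v", 1:m)))
    for (j in seq_len(m)) {
      ref <- sample(c("A", "C", "G", "T"), 2)
      g <- c("0/0", normalize_call(ref[1], ref[1]),
             normalize_call(ref[1], ref[2]),
             normalize_call(ref[2], ref[2]))
      mat[, j] <- sample(g, n, replace = TRUE)
    }
    members <- data.frame(pedigree = paste0("F", 1:n), person = "P1",
                          father = NA, mother = NA, sex = "unknown")
    markers <- data.frame(marker = paste0("v", 1:m), chromosome = 1,
                          bp = seq_len(m) * 100)
    prefix <- tempfile()
    write_plink_bed(mat, members, markers, prefix)
    px <- read_plink_bed(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                         paste0(prefix, ".fam"))
    expect_identical(px$calls, mat)
  }
  # an all-missing marker is all 01 codes and reads back as missing
  mat <- matrix("0/0", 2, 1, dimnames = list(c("F1:P1", "F2:P1"), "v1"))
  members <- data.frame(pedigree = c("F1", "F2"), person = "P1",
                        father = NA, mother = NA, sex = "unknown")
  markers <- data.frame(marker = "v1", chromosome = 1, bp = 5)
  prefix <- tempfile()
  write_plink_bed(mat, members, markers, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 4)
  expect_identical(raw[4], as.raw(0x05))   # 01 01 packed low-first
  # more than two alleles is an error naming the marker
  bad <- matrix(c("A/C", "G/T"), 2, 1,
                dimnames = list(c("F1:P1", "F2:P1"), "vx"))
  expect_error(write_plink_bed(bad, members,
                               data.frame(marker = "vx", chromosome = 1,
                                          bp = 5), tempfile()),
               "vx")
})

test_that("exports from blocks and from rows of the same data are byte-identical", {
  x <- study_db(seed = 55)
  sel <- selection_spec(build = "1")
  p1 <- tempfile()
  ped1 <- export_genotypes(x$db, sel,
                           spec = export_spec(format = "plink_ped",
                                              prefix = p1))
  # re-import the ped text into an empty row store
  back <- read_plink_ped(ped1$files[1], ped1$files[2])
  db2 <- gdb_create()
  stopifnot(load_members(db2, x$st$members, mode = "commit")$committed)
  stopifnot(load_samples(db2, x$st$samples, mode = "commit")$committed)
  load_markers(db2, data.frame(name = x$st$map_table$marker),
               mode = "commit")
  load_marker_info(db2, data.frame(marker = x$st$map_table$marker,
                                   chromosome = x$st$map_table$chromosome,
                                   bp = x$st$map_table$bp,
                                   avg_cm = x$st$map_table$avg_cm),
                   build = "1", mode = "commit")
  gdb_create_experiment(db2, "rows", "reimport")
  calls <- back$calls
  calls$allele1[calls$allele1 == "0"] <- "0"
  keep <- !(calls$allele1 == "0" & calls$allele2 == "0")
  r <- import_targeted_genotypes(db2, calls[keep, ], "rows", "reimport",
                                 mode = "commit")
  expect_true(r$committed)
  expect_identical(nrow(gdb_tables(db2, "genotypes")), sum(keep))
  p2 <- tempfile()
  ped2 <- export_genotypes(db2, sel,
                           spec = export_spec(format = "plink_ped",
                                              prefix = p2))
  expect_identical(readLines(ped2$files[1]), readLines(ped1$files[1]))
  expect_identical(readLines(ped2$files[2]), readLines(ped1$files[2]))
})

test_that("frequency reports match brute-force counts over the export", {
  x <- study_db(seed = 77)
  out <- export_genotypes(x$db, selection_spec(build = "1"),
                          spec = export_spec(prefix = tempfile()))
  fr <- out$freq
  for (mk in colnames(out$matrix)) {
    g <- out$matrix[, mk]
    expect_identical(fr$missing$n_missing[fr$missing$marker == mk],
                     sum(g == "0/0"))
    g <- g[g != "0/0"]
    al <- c(substr(g, 1, 1), substr(g, 3, 3))
    sub <- fr$alleles[fr$alleles$marker == mk, ]
    for (k in seq_len(nrow(sub))) {
      expect_identical(sub$count[k], sum(al == sub$allele[k]))
    }
    if (nrow(sub)) expect_equal(sum(sub$freq), 1)
  }
  # the single-member case: one A/C call gives 0.5 / 0.5
  m1 <- matrix("A/C", 1, 1, dimnames = list("F1:P1", "mk"))
  fr1 <- allele_frequencies(m1)
  expect_equal(fr1$alleles$freq, c(0.5, 0.5))
  expect_identical(fr1$alleles$allele, c("A", "C"))
})

test_that("streaming export writes the same ped lines as the in-memory path", {
  x <- study_db(seed = 91)
  sel <- selection_spec(build = "1")
  full <- export_genotypes(x$db, sel,
                           spec = export_spec(format = "plink_ped",
                                              prefix = tempfile()))
  stream <- export_genotypes(
    x$db, sel,
    spec = export_spec(format = "plink_ped", prefix = tempfile(),
                       per_person_streaming = TRUE,
                       collect_stats = FALSE))
  expect_identical(readLines(stream$files[1]), readLines(full$files[1]))
  expect_null(stream$matrix)
  expect_error(export_spec(per_person_streaming = TRUE,
                           collect_stats = TRUE), "streaming")
})
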