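test_that("targeted import inserts normalized rows and flags duplicates", {
  db <- tiny_db()
  g <- data.frame(pedigree = rep(c("F1", "F2"), each = 3),
                  person = rep("P1", 6),
                  marker = rep(c("rs1", "rs2", "rs3"), 2),
                  allele1 = c("C", "A", "G", "A", "1", "T"),
                  allele2 = c("A", "A", "G", "C", "2", "G"))
  r <- import_targeted_genotypes(db, g, "expA", "tech1", mode = "commit")
  expect_true(r$committed)
  expect_identical(r$n_new, 6L)
  gt <- gdb_tables(db, "genotypes")
  expect_identical(nrow(gt), 6L)
  # stored normalized: no unordered pair anywhere
  expect_true(all(gv_allele_rank(gt$allele1) <=
                    gv_allele_rank(gt$allele2)))
  # re-import with one discordant call: warning, conflict kept as duplicate
  g2 <- g[1:3, ]
  g2$allele1[1] <- "G"
  g2$allele2[1] <- "G"
  r2 <- import_targeted_genotypes(db, g2, "expA", "tech1",
                                  mode = "commit")
  expect_true(r2$committed)
  expect_match(r2$warnings, "different genotype")
  expect_identical(r2$n_changed, 1L)
  expect_identical(r2$n_new, 1L)          # only the discordant row
  expect_identical(nrow(gdb_tables(db, "genotypes")), 7L)
  # the within-experiment duplicate now conflicts at equal trust
  out <- export_genotypes(db, selection_spec(build = "1"),
                          spec = export_spec(prefix = tempfile()))
  expect_identical(out$matrix["F1:P1", "rs1"], "0/0")
  expect_identical(nrow(out$conflicts), 1L)
})

test_that("targeted import resolves subjects through samples and aliases", {
  db <- tiny_db()
  g <- data.frame(sample = "S_F1_P4", marker = "rs1", genotype = "AC")
  r <- import_targeted_genotypes(db, g, "expA", "tech1", mode = "commit")
  expect_true(r$committed)
  expect_identical(gdb_tables(db, "genotypes")$member_id,
                   resolve_member(db, "F1", "P4"))
  r <- import_targeted_genotypes(
    db, data.frame(sample = "nope", marker = "rs1", genotype = "AC"),
    "expA", "tech1", mode = "commit")
  expect_false(r$committed)
  expect_match(r$errors, "unknown sample")
})

test_that("wide and file-based targeted layouts agree with the long layout", {
  db1 <- tiny_db()
  wide <- data.frame(pedigree = c("F1", "F1"), person = c("P1", "P2"),
                     rs1 = c("A/C", "C/C"), rs2 = c("G/T", "0/0"),
                     check.names = FALSE)
  r <- import_targeted_genotypes(db1, wide, "expA", "tech1",
                                 mode = "commit")
  expect_true(r$committed)
  db2 <- tiny_db()
  long <- data.frame(pedigree = rep(c("F1", "F1"), 2),
                     person = rep(c("P1", "P2"), 2),
                     marker = rep(c("rs1", "rs2"), each = 2),
                     genotype = c("A/C", "C/C", "G/T", "0/0"))
  import_targeted_genotypes(db2, long, "expA", "tech1", mode = "commit")
  sel <- selection_spec(build = "1")
  m1 <- export_genotypes(db1, sel,
                         spec = export_spec(prefix = tempfile()))$matrix
  m2 <- export_genotypes(db2, sel,
                         spec = export_spec(prefix = tempfile()))$matrix
  expect_identical(m1, m2)
})

test_that("the same cohort imported via either genome-wide dialect stores identical blocks", {
  dir <- tempfile("study_")
  st <- make_study(dir, n_pedigrees = 2, n_children = 1,
                   markers_per_chromosome = c(`1` = 5, `2` = 3),
                   missing_rate = 0.1, seed = 9)
  setup <- function() {
    db <- gdb_create()
    stopifnot(load_members(db, st$members, mode = "commit")$committed)
    stopifnot(load_samples(db, st$samples, mode = "commit")$committed)
    gdb_create_experiment(db, "gw", "chip")
    db
  }
  db_i <- setup()
  r <- import_per_sample_files(db_i, st$map, st$per_sample, "gw",
                               layout = "chip", block_size = 4,
                               build = "1", mode = "commit")
  expect_true(r$committed)
  expect_length(r$errors, 0L)
  db_a <- setup()
  r <- import_multi_sample_file(db_a, st$multi_sample, st$map, "gw",
                                layout = "chip", block_size = 4,
                                build = "1", mode = "commit")
  expect_true(r$committed)
  cols <- c("sample_id", "experiment_id", "layout", "chromosome",
            "block_index", "payload")
  expect_identical(gdb_tables(db_i, "genotypeblocks")[cols],
                   gdb_tables(db_a, "genotypeblocks")[cols])
  # idempotence: re-running the unchanged import writes nothing
  before <- gdb_snapshot(db_i)
  r <- import_per_sample_files(db_i, st$map, st$per_sample, "gw",
                               layout = "chip", block_size = 4,
                               build = "1", mode = "commit")
  expect_identical(r$n_new, 0L)
  expect_tables_equal(db_i, before)
  # a sample file mismatching the mapping rolls the run back
  broken <- st$per_sample
  bad <- utils::read.delim(broken[[1]], colClasses = "character")
  data.table::fwrite(bad[-1, ], broken[[1]], sep = "\t")
  db_b <- setup()
  before <- gdb_snapshot(db_b)
  r <- import_per_sample_files(db_b, st$map, broken, "gw",
                               layout = "chip", block_size = 4,
                               build = "1", mode = "commit")
  expect_false(r$committed)
  expect_match(r$errors, "does not match the marker mapping")
  expect_tables_equal(db_b, before)
})

test_that("a zero-sample multi-sample file yields a report and no blocks", {
  db <- tiny_db()
  gdb_create_experiment(db, "gw", "chip")
  map <- data.frame(marker = c("x1", "x2"), chromosome = 1, bp = c(1, 2))
  wide <- data.frame(marker = c("x1", "x2"))
  r <- import_multi_sample_file(db, wide, map, "gw", layout = "chip",
                                block_size = 500, build = "1",
                                mode = "commit")
  expect_true(r$committed)
  expect_identical(nrow(gdb_tables(db, "genotypeblocks")), 0L)
})

test_that("PLINK binary export/import round-trips the logical matrix", {
  dir <- tempfile("study_")
  st <- make_study(dir, n_pedigrees = 2, n_children = 2,
                   markers_per_chromosome = c(`1` = 4, `2` = 2),
                   missing_rate = 0.15, seed = 21)
  db <- gdb_create()
  load_members(db, st$members, mode = "commit")
  load_samples(db, st$samples, mode = "commit")
  expect_true(load_trait(db, st$traits, "affection", "qualitative",
                         mode = "commit")$committed)
  gdb_create_experiment(db, "gw", "chip")
  r <- import_per_sample_files(db, st$map, st$per_sample, "gw",
                               layout = "chip", block_size = 3,
                               build = "1", mode = "commit")
  expect_true(r$committed)
  out <- export_genotypes(db, selection_spec(build = "1"),
                          spec = export_spec(format = "plink_bed",
                                             prefix = tempfile()))
  # magic bytes of the published binary format
  expect_identical(readBin(out$files[1], "raw", 3),
                   as.raw(c(0x6c, 0x1b, 0x01)))
  # re-import into a fresh database through the PLINK importer
  db2 <- gdb_create()
  r <- import_plink_binary(db2, out$files[1], out$files[2], out$files[3],
                           experiment = "reimport", technology = "PLINK",
                           layout = "chip2", block_size = 3, build = "1",
                           mode = "commit")
  expect_false(r$committed)   # experiment must exist first
  gdb_create_experiment(db2, "reimport", "PLINK")
  r <- import_plink_binary(db2, out$files[1], out$files[2], out$files[3],
                           experiment = "reimport", layout = "chip2",
                           block_size = 3, build = "1", mode = "commit")
  expect_true(r$committed)
  out2 <- export_genotypes(db2, selection_spec(build = "1"),
                           spec = export_spec(prefix = tempfile()))
  m1 <- out$matrix
  m2 <- out2$matrix
  # members are keyed pedigree:person in both stores
  expect_identical(m2[rownames(m1), colnames(m1)], m1)
  # fam parental links were materialized
  mem <- gdb_tables(db2, "members")
  kid <- mem[mem$person == "P3" & mem$pedigree == "F01", ]
  expect_identical(kid$father, "P1")
  expect_identical(kid$mother, "P2")
  # and the phenotype column became a qualitative trait
  expect_identical(nrow(find_notes(db2, "nothing")), 0L)
  tm <- gdb_tables(db2, "traitmeta")
  expect_true("affection" %in% tm$name)
})

test_that("corrupt PLINK binary input is refused", {
  bad <- tempfile(fileext = ".bed")
  writeBin(as.raw(c(0x00, 0x01, 0x02, 0x03)), bad)
  bim <- tempfile(fileext = ".bim")
  fam <- tempfile(fileext = ".fam")
  writeLines("1\tsnp1\t0\t100\tA\tC", bim)
  writeLines("F1 P1 0 0 1 -9", fam)
  expect_error(read_plink_bed(bad, bim, fam), "magic")
  # individual-major mode byte
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0xff)), bad)
  expect_error(read_plink_bed(bad, bim, fam), "individual-major")
})
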