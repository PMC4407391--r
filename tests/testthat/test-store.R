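test_that("commit only adds new information and is idempotent", {
  db <- gdb_create()
  mk <- data.frame(name = paste0("rs", 1:4))
  info <- data.frame(marker = mk$name, chromosome = 1, bp = 1:4 * 100)
  expect_true(load_markers(db, mk, mode = "commit")$committed)
  r1 <- load_marker_info(db, info, build = "1", mode = "commit")
  expect_true(r1$committed)
  expect_identical(r1$n_new, 4L)
  before <- gdb_snapshot(db)
  # same file again: no changes at all
  r2 <- load_marker_info(db, info, build = "1", mode = "commit")
  expect_identical(r2$n_new, 0L)
  expect_identical(r2$n_changed, 0L)
  expect_tables_equal(db, before)
  # extended file: just the new entries
  load_markers(db, data.frame(name = "rs5"), mode = "commit")
  info2 <- rbind(info, data.frame(marker = "rs5", chromosome = 2,
                                  bp = 999))
  r3 <- load_marker_info(db, info2, build = "1", mode = "commit")
  expect_identical(r3$n_new, 1L)
  mi <- gdb_tables(db, "marker_info")
  expect_identical(nrow(mi), 5L)
  expect_identical(mi$bp[1:4], c(100, 200, 300, 400))
})

test_that("a changed record warns under commit and only changes under replace/update", {
  db <- gdb_create()
  load_markers(db, data.frame(name = "rs1"), mode = "commit")
  info <- data.frame(marker = "rs1", chromosome = 1, bp = 100)
  load_marker_info(db, info, build = "1", mode = "commit")
  revised <- data.frame(marker = "rs1", chromosome = 1, bp = 150)
  # compare mode reports the difference without touching the store
  rc <- gdb_load(db, "marker_info",
                 transform(revised, build = "1"), "compare")
  expect_identical(rc$n_changed, 1L)
  expect_match(rc$warnings, "differs")
  expect_identical(gdb_tables(db, "marker_info")$bp, 100)
  # plain commit warns and leaves the stored value alone
  r <- load_marker_info(db, revised, build = "1", mode = "commit")
  expect_true(r$committed)
  expect_identical(r$n_changed, 1L)
  expect_match(r$warnings, "NOT modified")
  expect_identical(gdb_tables(db, "marker_info")$bp, 100)
  # replace rewrites it
  r <- load_marker_info(db, revised, build = "1",
                        mode = "commit_replace")
  expect_true(r$committed)
  expect_identical(gdb_tables(db, "marker_info")$bp, 150)
  # update modifies in place
  r <- load_marker_info(db, data.frame(marker = "rs1", chromosome = 1,
                                       bp = 175),
                        build = "1", mode = "commit_update")
  expect_true(r$committed)
  expect_identical(gdb_tables(db, "marker_info")$bp, 175)
})

test_that("replace of a referenced member is refused but update succeeds", {
  db <- tiny_db()
  gdb_create_experiment(db, "expX", "tech1")
  r <- import_targeted_genotypes(
    db, data.frame(pedigree = "F1", person = "P3", marker = "rs1",
                   genotype = "A/C"),
    "expX", "tech1", mode = "commit")
  expect_true(r$committed)
  changed <- data.frame(pedigree = "F1", person = "P3", father = "0",
                        mother = "0", sex = "1")
  before <- gdb_snapshot(db)
  r <- load_members(db, changed, mode = "commit_replace")
  expect_false(r$committed)
  expect_match(r$errors, "referenced")
  expect_tables_equal(db, before)
  r <- load_members(db, changed, mode = "commit_update")
  expect_true(r$committed)
  mem <- gdb_tables(db, "members")
  expect_true(is.na(mem$father[mem$pedigree == "F1" &
                                 mem$person == "P3"]))
  # the member id survived the update, so the genotype still resolves
  expect_identical(gdb_tables(db, "genotypes")$member_id,
                   resolve_member(db, "F1", "P3"))
})

test_that("delete mode removes exactly the listed records", {
  db <- gdb_create()
  load_markers(db, data.frame(name = paste0("rs", 1:5)), mode = "commit")
  r <- gdb_load(db, "markers", data.frame(name = c("rs2", "rs4")),
                "delete")
  expect_identical(r$n_deleted, 2L)
  expect_identical(gdb_tables(db, "markers")$name,
                   c("rs1", "rs3", "rs5"))
})

test_that("dry runs and failed commits leave the store byte-identical", {
  db <- tiny_db()
  before <- gdb_snapshot(db)
  r <- load_markers(db, data.frame(name = "rs99"), mode = "dry_run")
  expect_identical(r$n_new, 1L)
  expect_false(r$committed)
  expect_tables_equal(db, before)
  # injected failure mid-run: second row invalid -> everything rolls back
  bad <- data.frame(marker = c("rs1", "rs2"), chromosome = c(1, 1),
                    bp = c(500, -3))
  r <- load_marker_info(db, bad, build = "2", mode = "commit")
  expect_false(r$committed)
  expect_length(r$errors, 1L)
  expect_tables_equal(db, before)
  # same for the targeted importer: unknown marker voids the whole file
  gdb_create_experiment(db, "expZ", "tech1")
  before2 <- gdb_snapshot(db)
  r <- import_targeted_genotypes(
    db, data.frame(pedigree = c("F1", "F1"), person = c("P1", "P2"),
                   marker = c("rs1", "rs_unknown"),
                   genotype = c("A/C", "A/C")),
    "expZ", "tech1", mode = "commit")
  expect_false(r$committed)
  expect_identical(nrow(gdb_tables(db, "genotypes")), 0L)
  expect_tables_equal(db, before2)
})

test_that("delete_experiment removes one experiment's data only", {
  db <- tiny_db()
  g <- data.frame(pedigree = rep(c("F1", "F1"), each = 3),
                  person = rep(c("P1", "P2"), each = 3),
                  marker = rep(c("rs1", "rs2", "rs3"), 2),
                  genotype = c("A/C", "A/A", "C/C", "A/C", "A/C", "C/C"))
  for (e in c("expA", "expB")) {
    expect_true(import_targeted_genotypes(db, g, e, "tech1",
                                          mode = "commit")$committed)
  }
  sel <- selection_spec(build = "1")
  # oracle: a store that only ever saw expB
  ref <- tiny_db()
  expect_true(import_targeted_genotypes(ref, g, "expB", "tech1",
                                        mode = "commit")$committed)
  n <- gdb_delete_experiment(db, "expA")
  expect_identical(n, 6L)
  expect_error(gdb_delete_experiment(db, "nope"), "unknown experiment")
  expect_identical(gdb_delete_experiment(db, "expA"), 0L)
  out_db <- export_genotypes(db, sel,
                             spec = export_spec(prefix = tempfile()))
  out_ref <- export_genotypes(ref, sel,
                              spec = export_spec(prefix = tempfile()))
  expect_identical(out_db$matrix, out_ref$matrix)
})

test_that("active flags hide and restore genotypes without deleting them", {
  db <- tiny_db()
  g <- data.frame(pedigree = "F1", person = "P1",
                  marker = c("rs1", "rs2"), genotype = c("A/C", "G/G"))
  import_targeted_genotypes(db, g, "expA", "tech1", mode = "commit")
  sel <- selection_spec(build = "1")
  base <- export_genotypes(db, sel,
                           spec = export_spec(prefix = tempfile()))
  n <- gdb_set_active(db, "expA", markers = "rs2", active = FALSE)
  expect_identical(n, 1L)
  off <- export_genotypes(db, sel,
                          spec = export_spec(prefix = tempfile()))
  expect_identical(off$matrix["F1:P1", "rs2"], "0/0")
  expect_identical(off$matrix["F1:P1", "rs1"], "A/C")
  # involution: reactivating restores the original export
  gdb_set_active(db, "expA", markers = "rs2", active = TRUE)
  back <- export_genotypes(db, sel,
                           spec = export_spec(prefix = tempfile()))
  expect_identical(back$matrix, base$matrix)
  # deactivating everything empties the genotype view
  gdb_set_active(db, "expA", active = FALSE)
  none <- export_genotypes(db, sel,
                           spec = export_spec(prefix = tempfile()))
  expect_true(all(none$matrix == "0/0"))
  expect_identical(gdb_set_active(db, "expA", markers = "rs5",
                                  active = FALSE), 0L)
})

test_that("a database survives the save/open round trip", {
  db <- tiny_db()
  store_note(db, c("load", "qc"), "first load",
             payload = c("line1", "tab\there"))
  dir <- tempfile("gvdb_")
  gdb_save(db, dir)
  db2 <- gdb_open(dir)
  expect_identical(gdb_tables(db2), gdb_tables(db))
  # id counters restored: new inserts do not collide
  load_markers(db2, data.frame(name = "rs6"), mode = "commit")
  ids <- gdb_tables(db2, "markers")$marker_id
  expect_identical(anyDuplicated(ids), 0L)
})
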