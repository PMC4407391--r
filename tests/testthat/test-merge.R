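test_that("allele maps relabel calls and keep 0/0 fixed", {
  m <- data.frame(from_allele = c("1", "2"), to_allele = c("A", "C"))
  expect_identical(apply_allele_map("1/2", m), "A/C")
  expect_identical(apply_allele_map("0/0", m), "0/0")
  expect_identical(apply_allele_map("1/1", m), "A/A")
  expect_identical(apply_allele_map(c("1/2", "2/2", "G/T"), m),
                   c("A/C", "C/C", "G/T"))
  bad <- data.frame(from_allele = c("1", "2"), to_allele = c("A", "A"))
  expect_error(apply_allele_map("1/2", bad), "injective")
  r <- load_allele_map(tiny_db(), data.frame(marker = "rs1",
                                             from_allele = "0",
                                             to_allele = "A"),
                       "expA", mode = "commit")
  expect_match(r$errors, "missing code")
})

test_that("conflict resolution follows the trust-then-consensus rule", {
  expect_identical(resolve_calls(c("0/0", "A/C")),
                   list(call = "A/C", conflict = FALSE))
  expect_identical(resolve_calls(c("1/2", "G/T")),
                   list(call = "0/0", conflict = TRUE))
  expect_identical(resolve_calls(c("1/2", "G/T"), trust = c(1, 2)),
                   list(call = "G/T", conflict = FALSE))
  expect_identical(resolve_calls(character(0)),
                   list(call = "0/0", conflict = FALSE))
  expect_identical(resolve_calls(c("0/0", "0/0")),
                   list(call = "0/0", conflict = FALSE))
  # a trusted missing call does not beat a measured one: 0/0 is dropped
  # before the trust filter
  expect_identical(resolve_calls(c("0/0", "A/C"), trust = c(5, 0)),
                   list(call = "A/C", conflict = FALSE))
  # trust ties among discordant calls mask the genotype
  expect_identical(resolve_calls(c("A/A", "A/C", "0/0"),
                                 trust = c(2, 2, 9)),
                   list(call = "0/0", conflict = TRUE))
})

test_that("resolution is order-independent and never invents a genotype", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(1:5, 1)
    calls <- random_calls(n, alleles = c("0", "A", "C", "1", "2"))
    trust <- sample(0:2, n, replace = TRUE)
    base <- resolve_calls(calls, trust)
    perm <- sample(n)
    expect_identical(resolve_calls(calls[perm], trust[perm]), base)
    expect_true(base$call %in% c(calls, "0/0"))
    if (base$conflict) expect_identical(base$call, "0/0")
  }
})

test_that("conflicts equal the off-diagonal non-missing mass of the agreement matrix", {
  set.seed(31)
  for (i in 1:20) {
    n <- 40
    a <- random_calls(n, alleles = c("0", "A", "C"))
    b <- random_calls(n, alleles = c("0", "A", "C"))
    am <- agreement_matrix(a, b)
    off <- sum(am[-1, -1]) - sum(diag(am[-1, -1, drop = FALSE]))
    conf <- sum(mapply(function(x, y) resolve_calls(c(x, y))$conflict,
                       a, b))
    expect_identical(conf, off)
  }
  expect_error(agreement_matrix("A/A", c("A/A", "C/C")), "length")
})

test_that("agreement matrices label rows with the first experiment", {
  a <- c("A/A", "A/A", "A/C")
  b <- c("A/A", "A/C", "0/0")
  am <- agreement_matrix(a, b, experiments = c("e1", "e2"))
  expect_identical(rownames(am), c("0/0", "A/A", "A/C"))
  expect_identical(am["A/A", "A/C"], 1L)
  expect_identical(am["A/C", "0/0"], 1L)
  expect_identical(sum(am), 3L)
  # identical vectors give a diagonal-only matrix
  am2 <- agreement_matrix(a, a)
  expect_identical(sum(am2) - sum(diag(am2)), 0L)
})

test_that("stored agreement uses both representations and allele maps", {
  db <- tiny_db()
  gdb_create_experiment(db, "gw", "chip")
  # expA types three members in the row store with numeric labels
  import_targeted_genotypes(
    db, data.frame(pedigree = "F1", person = c("P1", "P2", "P3"),
                   marker = "rs4", genotype = c("1/1", "1/2", "2/2")),
    "expA", "tech1", mode = "commit")
  # gw types two of them (and one more) in the block store with letters
  map <- data.frame(marker = c("rs4", "rs5"), chromosome = 2,
                    bp = c(100, 250))
  gen <- function(g1, g2) data.frame(marker = c("rs4", "rs5"),
                                     genotype = c(g1, g2))
  r <- import_per_sample_files(
    db, map, list(S_F1_P1 = gen("A/A", "G/G"),
                  S_F1_P2 = gen("A/C", "G/G"),
                  S_F1_P4 = gen("C/C", "G/T")),
    "gw", layout = "chip", block_size = 500, build = "1",
    mode = "commit")
  expect_true(r$committed)
  expect_error(gdb_agreement(db, "expA", "expA"), "distinct")
  am <- gdb_agreement(db, "expA", "gw", markers = "rs4",
                      apply_maps = FALSE)
  expect_identical(am["1/1", "A/A"], 1L)
  expect_identical(am["1/2", "A/C"], 1L)
  expect_identical(am["2/2", "0/0"], 1L)   # P3 untyped in gw
  expect_identical(am["0/0", "C/C"], 1L)   # P4 untyped in expA
  expect_identical(sum(am), 4L)
  # with the allele map applied, expA's labels line up with gw's
  load_allele_map(db, data.frame(marker = "rs4",
                                 from_allele = c("1", "2"),
                                 to_allele = c("A", "C")),
                  "expA", mode = "commit")
  am2 <- gdb_agreement(db, "expA", "gw", markers = "rs4")
  expect_identical(am2["A/A", "A/A"], 1L)
  expect_identical(am2["A/C", "A/C"], 1L)
})

test_that("preferred samples silence a member's other samples", {
  db <- tiny_db()
  # second sample for F1/P1, preferred
  r <- load_samples(db, data.frame(sample_name = "S_F1_P1_redo",
                                   pedigree = "F1", person = "P1",
                                   preferred = "1"), mode = "commit")
  expect_true(r$committed)
  import_targeted_genotypes(
    db, data.frame(sample = c("S_F1_P1", "S_F1_P1_redo"),
                   marker = "rs1", genotype = c("A/A", "C/C")),
    "expA", "tech1", mode = "commit")
  out <- export_genotypes(db, selection_spec(build = "1"),
                          merge_policy(),
                          export_spec(prefix = tempfile()))
  expect_identical(out$matrix["F1:P1", "rs1"], "C/C")
  expect_identical(nrow(out$conflicts), 0L)
  # ignoring preference, the two samples conflict at equal trust
  out2 <- export_genotypes(db, selection_spec(build = "1"),
                           merge_policy(honor_preferred_sample = FALSE),
                           export_spec(prefix = tempfile()))
  expect_identical(out2$matrix["F1:P1", "rs1"], "0/0")
  expect_identical(nrow(out2$conflicts), 1L)
  # the surface function mirrors the pipeline behaviour
  smp <- gdb_tables(db, "samples")
  smp <- smp[smp$member_id == resolve_member(db, "F1", "P1"), ]
  calls <- data.frame(sample_id = smp$sample_id, call = c("A/A", "C/C"))
  expect_identical(select_sample_calls(calls, smp)$call, "C/C")
  expect_identical(nrow(select_sample_calls(calls, smp,
                                            honor_preferred = FALSE)),
                   2L)
})

test_that("marker-level trust overrides beat experiment trust", {
  db <- tiny_db(trust = c(expA = 1L, expB = 0L))
  import_targeted_genotypes(
    db, data.frame(pedigree = "F1", person = "P1",
                   marker = c("rs1", "rs2"), genotype = c("A/A", "A/A")),
    "expA", "tech1", mode = "commit")
  import_targeted_genotypes(
    db, data.frame(pedigree = "F1", person = "P1",
                   marker = c("rs1", "rs2"), genotype = c("C/C", "C/C")),
    "expB", "tech1", mode = "commit")
  # expA wins everywhere by experiment trust
  out <- export_genotypes(db, selection_spec(build = "1"),
                          spec = export_spec(prefix = tempfile()))
  expect_identical(unname(out$matrix["F1:P1", c("rs1", "rs2")]),
                   c("A/A", "A/A"))
  # demoting expA at rs2 hands that marker to expB
  pol <- merge_policy(overrides = data.frame(experiment = "expA",
                                             marker = "rs2",
                                             trust = -1L))
  out2 <- export_genotypes(db, selection_spec(build = "1"), pol,
                           export_spec(prefix = tempfile()))
  expect_identical(unname(out2$matrix["F1:P1", c("rs1", "rs2")]),
                   c("A/A", "C/C"))
})
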