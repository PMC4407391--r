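Package: genovault
Title: Manage, Reconcile and Export Pedigree, Phenotype and Genotype Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A transactional data store for human-genetics studies that
    accumulate genotype data from multiple overlapping experiments.  Holds
    pedigree, phenotype, marker-map and genotype data; packs genome-wide
    genotypes into fixed-capacity per-chromosome blocks with a
    marker-to-(chromosome, block, offset) index; reconciles repeated
    genotyping of the same person and marker across experiments via allele
    relabelling, trust levels, active flags and preferred samples, with
    agreement-matrix diagnostics; and exports flexibly filtered subsets in
    columnar, PLINK ped/map, PLINK bed/bim/fam or Mega2-style formats.
    Includes a deterministic synthetic study generator so every pipeline
    stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
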