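# genovault

Pedigree, phenotype and genotype data management for human-genetics
studies that accumulate data from multiple overlapping experiments.

A study of a complex trait typically genotypes its cohort several
times: a genome-wide chip first, then targeted follow-up on a different
platform, with failed samples re-run under new names.  The resulting
data sets overlap in people and markers, and the overlaps disagree in
structured ways — genuine discordance, different allele labelling
schemes (`1/2` vs `A/C`), renamed markers, positions that move between
map builds.  `genovault` stores all of it without ever rewriting
original data, and produces one coherent, auditable genotype per person
and marker at export time.

Core machinery:

* **Transactional store** with a dry-run/commit/compare/replace/update/
  delete protocol: `commit` only adds new information (changed records
  warn and are left alone), and any error rolls the whole run back.
* **Block-packed genome-wide storage**: the genotypes of up to *B*
  consecutive markers of one chromosome for one sample are one record
  (default *B* = 500), with an index mapping each marker to its
  (chromosome, block, offset) slot — a chromosome with *m* markers
  occupies ⌈*m*/*B*⌉ blocks.  Targeted data stays row-per-genotype.
* **Conflict resolution**: for each (member, marker), missing calls are
  discarded, only calls at maximal trust survive (per-experiment trust,
  per-marker overrides), consensus is output and disagreement is masked
  to `0/0` and logged.  Per-experiment allele maps (`1→A, 2→C`),
  active flags and preferred samples feed the same pipeline, and
  experiment-pair **agreement matrices** audit it.
* **Flexible extraction**: include/exclude pedigrees and persons,
  pedigree completion (keep family structures intact), trait-value
  filters, marker lists resolved through aliases, chromosome and
  bp/cM range selection against a named map build, exclusion ranges,
  experiment/technology restriction — exported as columnar text,
  PLINK ped/map, PLINK bed/bim/fam, or a Mega2-style trio, with
  allele/genotype frequency reports.
* **Synthetic study generator** so the whole pipeline is testable from
  code alone.

## Worked example

The package ships a populated example database (`make_marker_lookup_fixture()`)
with one subject typed by a targeted experiment `Exp D` (row store) and
a genome-wide experiment `Exp F` (block store), a marker renamed over
time, and one marker moved to another chromosome by the current build.

```r
library(genovault)
fx <- make_marker_lookup_fixture()
db <- fx$db

# markers on chromosome 1 between 10 and 20 Mb (current build)
sel <- selection_spec(ranges = data.frame(chromosome = 1,
                                          lo = 10000000, hi = 20000000),
                      build = "b37")
select_markers(db, sel)[, c("name", "chromosome", "bp")]
#>       name chromosome      bp
#> 1 rs123451          1 1.2e+07
#> 2 rs123452          1 1.5e+07

# merge the two experiments at three markers and write a ped file
out <- export_genotypes(db,
  selection_spec(markers = c("rs123401", "rs123451", "rs123452"),
                 build = "b37"),
  merge_policy(),
  export_spec(format = "plink_ped", prefix = file.path(tempdir(), "demo")))
out$matrix
#>       rs123401 rs123451 rs123452
#> F1:P1 "A/C"    "0/0"    "A/C"
out$conflicts
#>   pedigree person   marker               detail
#> 1       F1     P1 rs123451 Exp D:1/2; Exp F:G/T
readLines(out$files[1])
#> [1] "F1 P1 0 0 1 -9 A C 0 0 A C"
```

At `rs123401` one experiment reports `0/0` and the other `A/C`, so the
measured value wins.  At `rs123451` the experiments disagree (`1/2` vs
`G/T`) at equal trust, so the genotype is masked to missing and the
conflict logged.  At `rs123452` both agree.  The renamed marker
resolves under either name (`resolve_marker(db, "rs34567")` equals
`resolve_marker(db, "rs456784")`), and although its blocks were stored
under chromosome 2, selecting chromosome 3 — its current position —
still finds its `G/T` call through the storage index.

The frequency report is counted over the exported matrix:

```r
out$freq$alleles
#>     marker allele count freq
#> 1 rs123401      A     1  0.5
#> 2 rs123401      C     1  0.5
#> 3 rs123452      A     1  0.5
#> 4 rs123452      C     1  0.5
```

A command-line front end (`exec/genovault`, a thin wrapper over
`dbv_run()`) exposes the loader family — `createdb`, `member`,
`sample`, `trait`, `newmarker`, `marker_info`, `allelemap`, `geno`,
`genoi`, `genoa`, `genok`, `genout`, … — driven by INI-style
configuration files, with timestamped log files and optional storage of
the run log as a database note.

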