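---
title: "Managing, reconciling and exporting multi-experiment genotype data"
author: "genovault"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing, reconciling and exporting multi-experiment genotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A genetic study of a complex human trait rarely genotypes its cohort
once.  A genome-wide chip run is typically followed by targeted custom
genotyping of interesting regions, sometimes on a different platform,
sometimes re-running failed samples under new sample names.  The
resulting data sets overlap in both people and markers, and the overlaps
misbehave in predictable ways: most repeated genotypes agree, a few
genuinely differ, whole experiments may report the same alleles under a
different labelling scheme (`1/2` where another platform says `A/C`),
marker names are merged or retired over time, and map positions move
between genome builds.  Downstream analysis needs one coherent genotype
per person and marker, produced by rules that are explicit, auditable and
reversible.

`genovault` is a data-management layer for exactly this situation.  It
stores pedigree structure, phenotypes, marker maps (several builds at
once), and genotypes from any number of experiments; it never rewrites
original data, instead resolving disagreements at export time; and it
emits analysis-ready subsets in columnar text, PLINK ped/map, PLINK
bed/bim/fam or a Mega2-style annotated trio.

## The data model

The store is relational: `members` (pedigree + person name, parent
references, sex), `member_aliases`, `samples` (with an optional
*preferred* flag per person), `traitmeta`/`traits` (qualitative or
quantitative, validated on load), `markers`/`marker_aliases`,
`marker_info` (chromosome, bp and cM positions, tagged by map build),
`technologies`/`experiments` (with an integer *trust* level),
`allele_map`, the row-per-genotype `genotypes` table, the block-packed
`genotypeblocks` table with its `snpblocks` index, and `notes`.

A genotype call is an **unordered** pair of single-character allele codes
over `{0, 1–9, A, C, G, T}`, stored in a fixed order (digits before
letters) so that comparison is deterministic; `0/0` is the missing
genotype.  A half-missing call (exactly one allele `0`) has no defined
meaning in any of the supported input dialects, so it is rejected as
malformed rather than silently repaired.

The backend is an in-package transactional table store: schema-typed data
frames held in an environment, with snapshot/restore providing atomic
rollback and a directory of quoted TSV files providing persistence.  All
mutation goes through operations that take a snapshot first and restore
it on any error, which is the property the commit protocol needs; the
store is single-writer by design.

## The commit protocol

Every loader follows the same protocol.  Without a committing mode the
run parses, validates and reports, and the store is untouched (`dry_run`;
`compare` additionally lists records whose stored payload differs from
the file).  `commit` **only adds new information**: records whose natural
key is already present but whose payload changed produce a warning and
are left alone, so committing the same file twice is a no-op and
committing an extended file adds just the new rows.  `commit_replace`
deletes-and-reinserts changed records — refused when the old row is still
referenced from other tables — while `commit_update` edits them in place,
keeping their ids, for exactly that referenced case.  `delete` removes
the listed records.  Any error in a committing run rolls the whole run
back; a run is never half-applied.

## Block-packed genome-wide storage

Targeted experiments (dozens to thousands of markers) are stored one
genotype per record.  That representation does not scale to chip data:
hundreds of thousands of markers times a thousand samples is hundreds of
millions of rows, and the per-record overhead of indexing and atomicity
dominates.  Genome-wide experiments therefore pack the genotypes of `B`
consecutive markers of one chromosome, for one sample, into a single
block record; a per-layout index (`snpblocks`) maps each marker to its
(chromosome, block index, offset) slot.

* Markers are ordered by (chromosome, bp) at load time and assigned
  consecutive slots; a chromosome with `m` markers occupies
  `ceiling(m/B)` blocks, and the trailing block is padded with `0/0`
  slots.  Padding is reserved space — it decodes to missing and is never
  emitted as data — so blocks are layout-complete even for an all-missing
  sample, unlike the row store, which skips missing genotypes entirely.
* The payload encoding is two characters per slot (the two allele
  codes), which supports the full allele alphabet including microsatellite-style
  numeric codes; a 2-bit SNP-specific packing would be an optimization,
  not a semantic change.
* `B` defaults to **500** genotypes per block.  Load cost is essentially
  flat for larger blocks while wasted padding grows without bound (every
  chromosome wastes up to `B − 1` slots), so 500 is the operating point;
  it is configurable per layout.
* The index records the chromosome **at load time**.  If a later map
  build moves a marker to another chromosome, its blocks stay where they
  were written; selection uses the current build's positions and the
  index translates back to the storage address.  This is deliberate:
  re-packing terabytes of blocks on every build change would violate the
  "never rewrite stored data" rule.
* A layout is keyed by name and shared: several experiments genotyped on
  the same chip reuse one index.  Re-registering a layout with a
  different marker set or block size is an error rather than a silent
  fork.

Three importers feed this structure — one file per sample
(Illumina-style), one wide file with a column per sample
(Affymetrix-style), and PLINK binary filesets — all through one shared
block-writing base, which is what makes cross-dialect equivalence a
structural guarantee rather than a coincidence.

## Reconciling repeated genotypes

At export time all calls for a (member, marker) pair are gathered from
both representations and collapsed in four stages:

1. **Active flags and preferred samples.**  Rows flagged inactive are
   invisible (the data stays in the store).  If a member has a preferred
   sample, the other samples' calls are silenced; otherwise all samples
   feed the merge and within-person discordance is handled like any
   other conflict.
2. **Allele maps.**  Per (experiment, marker) relabellings such as
   `1→A, 2→C` are applied to the gathered calls, never to stored data.
   Maps must be injective and may not touch the missing code.
3. **Trust.**  Missing calls are discarded first — a highly trusted
   experiment that failed to call a genotype should not erase a measured
   one — then only calls at the maximal trust level survive.  Trust is
   per experiment, overridable per (experiment, marker); an override may
   be lower than the experiment level, demoting a single marker.
4. **Consensus.**  If all survivors agree, that value is output.
   Otherwise the genotype is masked to `0/0`, flagged as a conflict and
   written to the conflict log with the contributing experiments and
   calls.  Trust ties among discordant calls mask; the merge never
   invents a genotype and is order-independent.

The agreement matrix is the audit view of this process: for an
experiment pair and marker, cell (g₁, g₂) counts members called g₁ by
the first and g₂ by the second, with absence counted as `0/0`.  Its
off-diagonal non-missing mass is exactly the set of members the merge
would mask at equal trust, and a matrix that is diagonal *after*
remapping but fully off-diagonal before it is the signature of a
labelling-scheme mismatch rather than genuine discordance.

## Selection semantics

Filters compose as intersections.  Member selection applies
include/exclude pedigree and person lists (exclusion wins on overlap),
then trait-value filters, then the typed-in-experiment restriction, and
finally — if requested — pedigree completion.  Completion closes the
pool over pedigree co-membership so that family structures needed for
linkage analysis stay intact; because structure is the point, the
closure may re-admit individuals that an earlier filter removed, and
trait filters deliberately run *before* completion (select the affected,
then pull in their families).

Marker selection resolves names through aliases, then filters by
chromosome and by bp or cM ranges, inclusive on both ends, using the
positions of the named build — the current view of the genome.  cM
selection skips markers without a genetic position, with a warning.
Output order is (chromosome, bp, name): total and deterministic, so
repeated exports are byte-comparable.  Exclusion ranges (optionally per
member) are applied to the call stream after gathering and before the
merge, so an excluded measurement can neither win nor cause a conflict;
with `drop_untyped_markers`, markers left with no observation disappear
from the output.

## Export dialects and statistics

Members are written in (pedigree, person) order and markers in map
order in every dialect, masked conflicts appearing as the dialect's
missing code.  For PLINK binary output A1 is the minor allele by
frequency with ties broken by allele-code order, and trailing pad bits
are zero, following the published format.  The Mega2-style trio is a
names file (with a version header), a tab-separated map file and a
pre-makeped pedigree file.  Allele and genotype frequencies are counted
over the exported matrix exactly as written; for very large extractions
a streaming mode processes one person's worth of data at a time and
gathers no statistics.

## The synthetic study generator

All tests and the acceptance computations run on generated data.
`make_study()` writes a mutually consistent fileset — nuclear pedigrees,
one sample per member, an affection trait, a marker map and the same
call matrix rendered in every import dialect — from a single integer
seed.  Genotypes are drawn per marker from a uniform allele frequency
under Hardy–Weinberg equilibrium, with independent per-call missingness;
`make_agreement_fixture()` realizes a joint genotype count matrix
exactly (counts, not rates); `make_layout_fixture()` builds marker maps
whose per-chromosome counts realize a prescribed block occupancy, and
errors when the requested total is infeasible for it.

What the generator does **not** emulate matters for interpreting green
tests: there is no linkage disequilibrium, no population structure, no
Mendelian-consistent transmission within families, no platform-specific
error modes and no informative missingness.  Passing tests therefore
demonstrate the correctness of storage, reconciliation and export
mechanics — byte-exact round trips, exact count laws, exact conflict
masking — not robustness to the biological texture of real cohorts.

Problem sizes are chosen so the full suite runs in well under a minute
of compute for everything except one deliberately full-scale check: the
block-allocation law is exercised at 1,058 samples × 25,143 markers
(66,654 block records), because the count law is the claim and scaling
it down would weaken it.  Round-trip and equivalence properties run at
desk scale (tens of members, a handful of markers) with randomized
content under fixed seeds.

## Numerical and degenerate-input choices

* Half-missing genotypes are rejected, not coerced.
* Sex accepts `1/2/0` and `M/F/U`; unknown parents are `0` or blank.
* Chromosomes are integers 1–26 with 23=X, 24=Y, 25=XY, 26=MT.
* `-`, `N`, `NA` and `.` in genotype input are configurable synonyms
  for the missing allele.
* Loading validates referential integrity eagerly: targeted genotypes
  require pre-registered markers and subjects; genome-wide mapping
  files auto-register their markers (they are the marker authority for
  chip content).
* A within-experiment duplicate with an identical call is skipped
  (idempotent commit); with a differing call it is stored, warned
  about, and left to the merge and agreement diagnostics.
* An experiment's trust defaults to 0; equal trust everywhere means
  plain consensus-or-mask.

## Limitations

No Mendelian-inheritance checking, no phasing, no sex-chromosome dosage
handling, no probabilistic consensus or quality-score weighting, no VCF
import/export, no intensity data, and a single-writer store without
user management.  These are boundaries, not oversights: the package's
job ends where analysis tools begin.
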