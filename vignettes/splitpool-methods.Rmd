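---
title: "Methods: demultiplexing split-pool barcoded single-nucleus RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demultiplexing split-pool barcoded single-nucleus RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitpool)
```

## The assay and the computational problem

Split-pool combinatorial barcoding labels nuclei without droplets: three
successive plate rounds attach one 8-nt well barcode each (round 1 by
in-well reverse transcription with 48 barcoded poly(dT) primers, rounds
2–3 by ligation), the round-3 oligo also contributing a unique molecular
identifier (UMI). A nucleus is therefore identified by its barcode
triple, and a cDNA molecule by the (cell, gene, UMI) triple. Sequencing
yields mate-synchronised pairs: read 1 (106 nt) is the transcript
fragment, read 2 (94 nt) holds the barcodes, arranged 5′→3′ as UMI (10
nt), bc3 (8 nt), linker A (30 nt), bc2 (8 nt), linker B (30 nt), bc1
(8 nt). `splitpool` converts raw pairs into a QC-filtered sparse gene ×
cell UMI matrix, with every intermediate result exposed as a tibble or
sparse matrix.

Two assumptions shape the design. First, segment positions in read 2 are
*fixed* within a run: the linkers are static, so their location anchors
every other segment. Second, barcode whitelists are known in advance
(the plate layouts); demultiplexing is assignment against whitelists,
never discovery.

## Position learning

Rather than trusting nominal offsets, `learn_positions()` scans up to
`learning_sample_size` (default 10,000) read-2 sequences for each linker
with at most `linker_mismatch` (default 1) mismatches, using
`Biostrings::vmatchPattern()`, and adopts the modal 0-based start
offset. Two guards make failure loud rather than silent: a linker found
in under 10% of sampled reads aborts learning (wrong config or wrong
file), and a modal offset explaining under half of the matches aborts
with the offset histogram (mixed layouts). UMI and bc3 offsets are
derived 5′ of linker A, bc2 3′ of it, and bc1 3′ of linker B, so a
non-default UMI length simply shifts the learned map. The UMI length
itself is a parameter (default 10 nt) carried by the layout object and
hard-coded nowhere else: the assay literature rarely states it and
designs vary.

## Barcode correction

Each observed 8-mer is corrected to the whitelist entry at minimal
distance, accepted iff that minimum is ≤ `e` (the `-e` flag, default 1)
and uniquely attained. Ties at the minimal qualifying distance discard
the read as ambiguous — the conservative choice, since a mis-assigned
read silently contaminates another cell whereas a discarded read only
costs depth. A whitelist's minimum pairwise Hamming distance `d_min` is
computed at load time and a warning is emitted when `d_min < 2e + 1`,
the condition under which single-error correction ceases to be
guaranteed unambiguous.

The default metric is Hamming (substitutions only): with
position-locked segments, an indel in a barcode desynchronises every
downstream segment, so substitution errors dominate the recoverable
class. A Levenshtein option exists for exploration; it scores the
fixed-width segment slice with `utils::adist()` and deliberately does
*not* re-anchor downstream segments around a putative indel — modelling
that would change the extraction contract for a case the position-locked
design cannot truly rescue. `N` counts as a mismatch against every base;
UMIs are taken verbatim, never corrected, and any non-ACGT symbol in the
UMI fails the read (`umi_invalid`). Failure reasons are positional: the
first failing segment in read-2 order (UMI, bc3, bc2, bc1) names the
reason, so `no_match_round3` dominates for junk reads.

Quality scores are ignored throughout: the correction radius `e = 1` is
already conservative and whitelist separation, not base quality, is the
binding constraint.

## Streaming, parallelism, filtering

`demultiplex()` partitions the pair stream into consecutive bins of
`bin_size` pairs (default 10^6) *by record index*, processes bins across
up to `threads` workers (`parallel::mclapply`), and concatenates results
in bin order. Because bin boundaries are index-based and extraction is
deterministic, the merged output is byte-identical for any thread
count — a property the test suite asserts on a 100,000-pair library at
1, 2, 4 and 8 threads. Metrics obey conservation by construction
(`reads_total = reads_pass + Σ fail reasons`) and the suite re-checks it
across randomised libraries.

The minimum-read filter (`-m`, default 200 — the production-scale
recommendation; low-depth barcodes are mostly barcode-collision and
ambient artefacts) retains cell labels with **at least** `m` passing
reads. Sub-threshold reads are removed from the annotated stream by
default (`drop_filtered`), since downstream matrices should not see
them; setting it `FALSE` keeps the stream and only records the retained
label set. An optional `sublibrary` tag is appended to every cell label
so matrices from separately indexed sublibraries can be merged without
label collisions. Filtering operates on post-demultiplex pass counts,
before any alignment.

## From reads to molecules

Alignment and feature assignment are external (a read → gene TSV is
consumed, keyed by the original read-1 identifier token), keeping the
package testable without an aligner. `join_assignments()` drops and
counts unassigned reads, then aggregates exact (cell, gene, UMI)
triples with their supporting read counts.

`collapse_umis()` offers two estimators of molecules per (cell, gene):

* `unique` — distinct UMI sequences; unbiased only with error-free UMIs.
* `directional` (default) — a directed graph over distinct UMIs with an
  edge `u → v` when Hamming(u, v) = 1 and
  `count(u) ≥ 2·count(v) − 1`; clusters are grown from unvisited roots
  in decreasing read-count order (ties broken lexicographically for
  determinism) and the cluster count is the molecule count. This is the
  standard directional-adjacency rule; the threshold absorbs
  sequencing-error satellites (expected at a fraction of the parent's
  count) without merging genuinely distinct UMIs of similar abundance.

`unique` is never below `directional` on the same group; the suite
verifies both estimators against an independent igraph-based
reachability oracle on 1,000 random groups.

`build_matrix()` emits a `dgCMatrix` with lexicographically sorted gene
and cell names, so the matrix is invariant to input order; the
MatrixMarket trio (`matrix.mtx`, `features.tsv`, `barcodes.tsv`) is the
on-disk exchange format.

## Quality control

`qc_filter()` applies, in a fixed order: (1) drop cells with total UMIs
< 500; (2) drop genes detected in < 10 *remaining* cells; (3) drop
cells with mitochondrial fraction > 5% or total UMIs > 15,000, both
computed on the matrix entering step 3. The order matters (gene
detection counts change after cell removal) and matches the order the
filters are conventionally listed in; outcomes at every boundary are
pinned by tests (499 vs 500 UMIs, 9 vs 10 cells, 5.0 vs 5.1% mito,
15,000 vs 15,001 UMIs). The mitochondrial fraction is computed on UMI
counts rather than raw reads: after collapse the matrix is the only
object available, and the ratio is near-identical when depth per
molecule is uniform. Upper-UMI filtering proxies doublet/multiplet
removal; dedicated doublet detection is out of scope.

## The simulator: what it emulates, what it does not

`simulate_library()` generates the structure the demultiplexer depends
on: three whitelisted barcode rounds at layout offsets separated by
static linkers, a verbatim UMI, per-base substitution errors (i.i.d. at
a stated rate, optionally restricted to barcode segments, or exactly
*k* substitutions in one randomly chosen barcode segment per read),
uniform-random junk reads at a stated fraction, and transcript fragments
for read 1. Cells sample well combinations *without replacement*, so
barcode collisions never confound evaluation. Defaults mirror the
assay: 48 wells in round 1 (the RT plate) and full 96-well plates for
rounds 2–3 (counts the protocol implies but does not print), 8-nt
barcodes, 10-nt UMI, 30-nt linkers (drawn once per simulation from the
seeded generator and recorded in the emitted config, since real linker
sequences are instrument-run constants not published with the assay),
106-nt read 1, 94-nt read 2. Generated whitelists enforce a minimum
pairwise Hamming distance (default 3 = `2e + 1` at the default
tolerance) by seeded greedy rejection; wide separations shrink the
attainable set (distance ≥ 5 supports ~16 wells of 8-mers under this
search), which the error-robustness tests respect by using 16-well
plates.

Deliberately *not* emulated: realistic transcriptomes (expression
gradients, splicing), ambient RNA, doublets, quality-score structure
(qualities are constant placeholders, as correction ignores them), PCR
duplication bias beyond uniform molecule resampling, and indel errors.
Passing tests therefore demonstrate the correctness of extraction,
correction, counting and filtering logic under the stated error model —
not robustness to every artefact of real libraries.

Ground truth is internally consistent by construction: the truth matrix
is the unique-collapse of the genuine reads' (cell, gene, UMI) triples,
so the headline end-to-end property — an error-free library reproduces
the truth matrix entry-for-entry through `demultiplex(e = 0)` →
`join_assignments()` → `collapse_umis("unique")` → `build_matrix()` —
is exact, not approximate.

## Problem sizes and numerical choices

The test and acceptance workloads use 200-cell × 50-gene libraries at
~100 reads/cell for round-trip and error-correction properties, a
1,000-cell, 100,000-pair library for thread-invariance, 20 randomised
small libraries for conservation, and 1,000 random UMI groups (sizes
1–50) for the collapse oracle — sizes chosen so each property is
exercised at meaningful scale while the whole suite runs in minutes on
one core. All comparisons of matrices and read sets are exact
(integer counts, set identity); no floating-point tolerances are needed
anywhere in the pipeline. Degenerate inputs are defined, not special-
cased: an empty library yields a 0 × 0 matrix, an empty UMI group zero
molecules, a single-entry whitelist an infinite minimum distance, and an
empty mitochondrial gene set disables the mito rule.

## Known limitations

* Hamming-only correction cannot rescue indel-containing barcodes; such
  reads fail cleanly rather than being re-anchored.
* The assignment-table interface assumes upstream mapping is unique per
  read; multi-mapped resolution policy belongs to the aligner stage.
* `filter_min_reads()` counts reads, not molecules; at very uneven
  depth per cell the two rankings can differ.
* The mitochondrial fraction is UMI-based (see above), a documented
  divergence from read-based definitions.
* Whole-file FASTQ ingestion favours simplicity over constant-memory
  streaming; `bin_size` bounds the working set of extraction, not of
  parsing. Libraries far beyond 10^7 pairs per sublibrary should be
  split upstream.
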