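# splitpool

Demultiplexing and UMI counting for split-pool combinatorially barcoded
single-nucleus RNA-seq libraries.

In split-pool (SPLiT-seq style) experiments, nuclei are labelled without
droplet partitioning: they pass through three successive barcoding plates
— an in-well reverse-transcription round with 48 well-specific barcoded
poly(dT) primers, then two ligation rounds — so that each nucleus ends up
tagged by a triple of 8-nt well barcodes plus a unique molecular
identifier (UMI). After paired-end sequencing, read 1 (106 nt) carries
the transcript fragment and read 2 (94 nt) carries, 5′→3′: the UMI, the
round-3 barcode, a static linker, the round-2 barcode, a second linker,
and the round-1 barcode. `splitpool` turns those raw FASTQ pairs into a
QC-filtered sparse gene × cell UMI count matrix. It is written for
anyone processing split-pool libraries who wants a testable, scriptable
pipeline with a ground-truthed simulator to verify it against.

## What it computes

1. **Position learning.** Barcode offsets are confirmed from the data:
   each static linker is located (allowing a configurable number of
   mismatches) in a sample of read-2 sequences, the modal start offset is
   adopted, and UMI/barcode offsets are derived from the linker anchors.
2. **Barcode correction.** Each observed 8-mer `b` is assigned to the
   whitelist entry `w` minimising the Hamming distance `d(b, w)`,
   accepted when `min d ≤ e` (the `-e` flag; default `e = 1`) and the
   minimiser is unique; ties are discarded as ambiguous. Correction is
   guaranteed unambiguous when the whitelist's minimum pairwise distance
   is at least `2e + 1`. Reads lacking a complete barcode triple + valid
   UMI are discarded with a positional failure reason.
3. **Mate annotation and filtering.** Passing reads have
   `|cell_label|UMI` appended to the read-1 identifier token; cell
   barcodes supported by fewer than `m` reads (`-m`, default 200) are
   dropped. Processing is binned (`bin_size` pairs per bin) and
   parallelised over `-n` threads with order-preserving merge, so output
   is identical for any thread count.
4. **UMI collapse.** Per (cell, gene), molecules are counted either as
   distinct UMIs (`unique`) or by the directional-adjacency rule: UMIs
   `u → v` are merged when they differ at one position and
   `count(u) ≥ 2·count(v) − 1`, clusters being grown from
   highest-count roots (`directional`, the default).
5. **QC.** Cells with `< 500` total UMIs, genes detected in `< 10`
   remaining cells, then cells with `> 5%` mitochondrial UMI fraction or
   `> 15000` UMIs are removed, in that order.

A seeded simulator (`simulate_library()`) generates paired FASTQ with
per-read ground truth (true cell, gene, UMI, injected errors, junk
reads), which `evaluate_run()` scores pipeline output against.

## Worked example

```r
library(splitpool)

params <- sim_params(n_cells = 100, n_genes = 30, seed = 42,
                     reads_per_cell = 60, junk_fraction = 0.05,
                     substitution_rate = 0.005, error_segments = NULL)
lib <- simulate_library(params)

res <- demultiplex(lib$r1, lib$r2, lib$whitelists, lib$layout,
                   config = demux_config(edit_tolerance = 1, min_reads = 20))
res <- filter_min_reads(res)
res
#> <demux_result>
#> <demux_metrics> 6000 reads: 5717 pass, 283 fail
#>   fail reasons: no_match_round3=254, no_match_round2=21, no_match_round1=8
#>   barcodes: 100 detected, 100 with >= 20 reads (5717 reads)

molecules <- join_assignments(res, lib$assignments)
mat <- build_matrix(collapse_umis(molecules, method = "directional"))
dim(mat)
#> [1]  30 100

evaluate_run(res, mat, lib$truth)
#> <splitpool_evaluation>
#>   read accuracy: 0.9974 (5732 genuine reads)
#>   junk pass rate: 0.0000 (268 junk reads)
#>   cell recovery: 1.0000 (100 / 100 cells)
#>   matrix agreement: 0.9921
```

The 6,000 simulated pairs include ~5% unparseable junk (failing mostly at
the first barcode checked, round 3) and a 0.5%/base substitution rate.
At `e = 1`, 99.7% of genuine reads land in their true cell, no junk read
is ever assigned, and all 100 cells pass the 20-read floor; the
directional count matrix agrees with the simulator's truth on 99.2% of
entries (the residual being reads whose two-error barcodes were
unrecoverable). `tidy()`, `glance()`, `autoplot()` and
`plot_barcode_rank()` summarise and visualise each result object.

The same pipeline is scriptable from a shell via the launcher in
`inst/scripts/splitpool`:

```sh
splitpool simulate --params params.cfg -o sim/
splitpool demux --r1 sim/r1.fastq.gz --r2 sim/r2.fastq.gz \
    --config sim/config.cfg -n 4 -e 1 -m 200 -o demux/
splitpool count --annotated-fastq demux/annotated_r1.fastq.gz \
    --assignments sim/assignments.tsv --method directional -o counts/
splitpool qc --matrix counts/ --mito-genes mito.txt -o qc/
splitpool evaluate --run demux/ --matrix counts/ --truth sim/truth -o eval/
```

Every run writes a `manifest.json` (version, resolved parameters, input
digests, outputs) sufficient to reproduce it.

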