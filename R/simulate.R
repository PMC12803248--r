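# Synthetic split-pool library simulator with per-read ground truth.

#' Simulation parameters
#'
#' Defines a synthetic split-pool library: how many cells and genes, the
#' per-round whitelists, the read-2 layout, sequencing depth, error and
#' junk rates. All randomness — whitelists, linkers, cell/well
#' combinations, molecules, errors — derives from `seed`, so identical
#' parameters yield byte-identical libraries.
#'
#' @param n_cells number of cells (well combinations, sampled without
#'   replacement so no two cells share a barcode triple).
#' @param n_genes number of genes.
#' @param seed mandatory RNG seed.
#' @param wells_per_round wells used in rounds 1..3 (default 48, 96, 96
#'   mirroring a 48-well RT round followed by full ligation plates).
#' @param min_distance minimum pairwise Hamming distance enforced when
#'   generating whitelists (ignored when `whitelists` is supplied).
#' @param barcode_length,umi_length,linker_length layout dimensions;
#'   defaults give the 94-nt read 2 of the assay (10 + 8 + 30 + 8 + 30
#'   + 8).
#' @param reads_per_cell mean reads per cell; exact when
#'   `reads_dispersion` is `NULL`, otherwise the mean of a negative
#'   binomial with `size = reads_dispersion`.
#' @param reads_dispersion optional negative-binomial size parameter.
#' @param molecules_per_cell distinct cDNA molecules per cell; each read
#'   samples one of its cell's molecules uniformly.
#' @param transcript_length length of each gene's synthetic transcript.
#' @param read1_length transcript read length (default 106).
#' @param substitution_rate per-base substitution probability
#'   (`error_mode = "rate"`).
#' @param error_mode `"rate"` for i.i.d. per-base substitutions across
#'   read 2 (optionally restricted via `error_segments`), or
#'   `"per_barcode"` for exactly `errors_per_read` substitutions at
#'   distinct positions within one randomly chosen barcode segment of
#'   every genuine read.
#' @param error_segments segments eligible for errors (`"rate"` mode
#'   restriction and `"per_barcode"` segment pool); default the three
#'   barcode segments; use `NULL` in rate mode for whole-read errors.
#' @param errors_per_read substitutions per read in `"per_barcode"` mode.
#' @param junk_fraction probability a read pair is unparseable junk
#'   (uniform random sequence on both mates).
#' @param whitelists optional list of three `barcode_whitelist`s.
#' @param layout optional `read_layout`; when `NULL`, linkers are drawn
#'   from the seeded generator and recorded in the emitted config so
#'   that simulation and demultiplexing always share one layout.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_cells, n_genes = 50L, seed,
                       wells_per_round = c(48L, 96L, 96L),
                       min_distance = 3L,
                       barcode_length = 8L, umi_length = 10L,
                       linker_length = 30L,
                       reads_per_cell = 100, reads_dispersion = NULL,
                       molecules_per_cell = 30L,
                       transcript_length = 500L, read1_length = 106L,
                       substitution_rate = 0,
                       error_mode = c("rate", "per_barcode"),
                       error_segments = c("bc1", "bc2", "bc3"),
                       errors_per_read = 1L,
                       junk_fraction = 0,
                       whitelists = NULL, layout = NULL) {
  error_mode <- match.arg(error_mode)
  if (missing(seed) || is.null(seed)) {
    abort("seed is mandatory", class = "splitpool_config_error")
  }
  if (substitution_rate < 0 || substitution_rate > 1 ||
      junk_fraction < 0 || junk_fraction > 1) {
    abort("rates must be in [0, 1]", class = "splitpool_config_error")
  }
  if (transcript_length < read1_length) {
    abort("transcript_length must be >= read1_length",
          class = "splitpool_config_error")
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 seed = as.integer(seed),
                 wells_per_round = as.integer(wells_per_round),
                 min_distance = as.integer(min_distance),
                 barcode_length = as.integer(barcode_length),
                 umi_length = as.integer(umi_length),
                 linker_length = as.integer(linker_length),
                 reads_per_cell = reads_per_cell,
                 reads_dispersion = reads_dispersion,
                 molecules_per_cell = as.integer(molecules_per_cell),
                 transcript_length = as.integer(transcript_length),
                 read1_length = as.integer(read1_length),
                 substitution_rate = substitution_rate,
                 error_mode = error_mode,
                 error_segments = error_segments,
                 errors_per_read = as.integer(errors_per_read),
                 junk_fraction = junk_fraction,
                 whitelists = whitelists,
                 layout = layout),
            class = "sim_params")
}

#' Simulate a split-pool library with ground truth
#'
#' Assembles read 2 as UMI + bc3 + linker A + bc2 + linker B + bc1 per
#' the layout (94 nt with defaults) and read 1 as a fragment of the
#' cell's assigned transcript, injects substitution errors and junk
#' reads, and records per-read ground truth (true cell, gene, UMI,
#' injected errors) plus the ground-truth count matrix (distinct
#' (cell, gene, UMI) triples among genuine reads).
#'
#' @param params a `sim_params`.
#' @param outdir optional directory; when given, writes `r1.fastq.gz`,
#'   `r2.fastq.gz`, the three whitelist TSVs, the matching demux config
#'   (`config.cfg`), the gene-assignment table (`assignments.tsv`) and
#'   a `truth/` directory (`reads.tsv` + ground-truth matrix trio).
#' @param demux_defaults a `demux_config` recorded in the emitted
#'   config file.
#' @return a `sim_library`: list with `r1`, `r2` (read tibbles),
#'   `truth` (list: `reads` tibble, `matrix`, `cells` tibble),
#'   `assignments`, `whitelists`, `layout`, `params` and, when written,
#'   `paths`.
#' @export
simulate_library <- function(params, outdir = NULL,
                             demux_defaults = demux_config(min_reads = 1L)) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)

  whitelists <- params$whitelists %||% lapply(1:3, function(r) {
    generate_whitelist(params$wells_per_round[[r]], round_id = r,
                       barcode_length = params$barcode_length,
                       min_distance = params$min_distance)
  })
  whitelists <- order_whitelists(whitelists)
  layout <- params$layout %||% splitpool_layout(
    linker_a = random_dna(1L, params$linker_length),
    linker_b = random_dna(1L, params$linker_length),
    umi_length = params$umi_length,
    barcode_length = params$barcode_length)
  validate_layout(layout, whitelists)

  n_combos <- prod(vapply(whitelists, nrow, integer(1)))
  if (params$n_cells > n_combos) {
    abort(sprintf("cannot place %d cells in %d distinct well combinations",
                  params$n_cells, n_combos), class = "splitpool_error")
  }
  combo <- sample.int(n_combos, params$n_cells)  # without replacement
  w1 <- (combo - 1L) %% nrow(whitelists[[1L]]) + 1L
  rest <- (combo - 1L) %/% nrow(whitelists[[1L]])
  w2 <- rest %% nrow(whitelists[[2L]]) + 1L
  w3 <- rest %/% nrow(whitelists[[2L]]) + 1L
  cells <- tibble(
    cell_label = paste(whitelists[[1L]]$well_id[w1],
                       whitelists[[2L]]$well_id[w2],
                       whitelists[[3L]]$well_id[w3], sep = "."),
    bc1 = whitelists[[1L]]$sequence[w1],
    bc2 = whitelists[[2L]]$sequence[w2],
    bc3 = whitelists[[3L]]$sequence[w3])

  gene_ids <- sprintf("gene%04d", seq_len(params$n_genes))
  transcripts <- random_dna(params$n_genes, params$transcript_length)

  reads_per_cell <- if (is.null(params$reads_dispersion)) {
    rep(as.integer(round(params$reads_per_cell)), params$n_cells)
  } else {
    rnbinom(params$n_cells, mu = params$reads_per_cell,
            size = params$reads_dispersion)
  }

  # one molecule table per cell; each read samples one of its molecules
  mol_cell <- rep(seq_len(params$n_cells), each = params$molecules_per_cell)
  mol_gene <- sample.int(params$n_genes,
                         params$n_cells * params$molecules_per_cell,
                         replace = TRUE)
  mol_umi <- random_dna(length(mol_cell), params$umi_length)

  read_cell <- rep(seq_len(params$n_cells), times = reads_per_cell)
  n_reads <- length(read_cell)
  read_mol <- (read_cell - 1L) * params$molecules_per_cell +
    sample.int(params$molecules_per_cell, n_reads, replace = TRUE)
  read_gene <- mol_gene[read_mol]
  read_umi <- mol_umi[read_mol]

  is_junk <- runif(n_reads) < params$junk_fraction
  read_id <- sprintf("read%07d", seq_len(n_reads))

  # read 1: transcript fragment (junk: uniform random)
  frag_start <- sample.int(params$transcript_length - params$read1_length + 1L,
                           n_reads, replace = TRUE)
  r1_seq <- substr(transcripts[read_gene], frag_start,
                   frag_start + params$read1_length - 1L)
  if (any(is_junk)) {
    r1_seq[is_junk] <- random_dna(sum(is_junk), params$read1_length)
  }

  # read 2: assembled per layout, then errors injected
  seg <- function(kind) layout_segment(layout, kind)
  r2_parts <- setNames(vector("list", nrow(layout)), layout$segment)
  r2_parts$umi <- read_umi
  r2_parts$bc3 <- cells$bc3[read_cell]
  r2_parts$linker_a <- rep(attr(layout, "linker_a"), n_reads)
  r2_parts$bc2 <- cells$bc2[read_cell]
  r2_parts$linker_b <- rep(attr(layout, "linker_b"), n_reads)
  r2_parts$bc1 <- cells$bc1[read_cell]
  ord <- layout$segment[order(layout$start)]
  r2_seq <- do.call(paste0, r2_parts[ord])

  err <- inject_errors(r2_seq, layout, params, genuine = !is_junk)
  r2_seq <- err$sequences
  if (any(is_junk)) {
    r2_len <- attr(layout, "min_read2_length")
    r2_seq[is_junk] <- random_dna(sum(is_junk), r2_len)
  }

  r1 <- tibble(id = read_id, sequence = r1_seq,
               quality = strrep("I", nchar(r1_seq)))
  r2 <- tibble(id = read_id, sequence = r2_seq,
               quality = strrep("I", nchar(r2_seq)))

  truth_reads <- tibble(
    read_id = read_id,
    cell_label = ifelse(is_junk, NA_character_, cells$cell_label[read_cell]),
    gene_id = ifelse(is_junk, NA_character_, gene_ids[read_gene]),
    umi = ifelse(is_junk, NA_character_, read_umi),
    is_junk = is_junk,
    injected_errors = ifelse(is_junk, "", err$labels))

  genuine <- truth_reads %>% filter(!.data$is_junk)
  truth_counts <- genuine %>%
    distinct(.data$cell_label, .data$gene_id, .data$umi) %>%
    count(.data$cell_label, .data$gene_id, name = "molecules")
  truth_matrix <- build_matrix(truth_counts)
  truth_cells <- genuine %>%
    count(.data$cell_label, name = "reads") %>%
    left_join(genuine %>%
                distinct(.data$cell_label, .data$gene_id, .data$umi) %>%
                count(.data$cell_label, name = "molecules"),
              by = "cell_label")

  assignments <- genuine %>%
    select(read_id = "read_id", gene_id = "gene_id")

  out <- structure(list(
    r1 = r1, r2 = r2,
    truth = list(reads = truth_reads, matrix = truth_matrix,
                 cells = truth_cells),
    assignments = assignments,
    whitelists = whitelists, layout = layout, params = params),
    class = "sim_library")

  if (!is.null(outdir)) {
    out$paths <- write_sim_library(out, outdir,
                                   demux_defaults = demux_defaults)
  }
  out
}

# Inject substitution errors into genuine read-2 sequences; returns the
# mutated sequences plus a per-read "segment:pos" label string.
#' @noRd
inject_errors <- function(sequences, layout, params, genuine) {
  labels <- rep("", length(sequences))
  idx <- which(genuine)
  if (!length(idx)) {
    return(list(sequences = sequences, labels = labels))
  }
  seg_tbl <- layout[order(layout$start), ]
  pos_segment <- rep(seg_tbl$segment, seg_tbl$length)  # 1-based pos -> kind
  if (params$error_mode == "rate") {
    if (params$substitution_rate == 0) {
      return(list(sequences = sequences, labels = labels))
    }
    eligible <- if (is.null(params$error_segments)) {
      seq_along(pos_segment)
    } else {
      which(pos_segment %in% params$error_segments)
    }
    m <- seq_char_matrix(sequences[idx])  # len x n
    hit <- matrix(FALSE, nrow = nrow(m), ncol = ncol(m))
    hit[eligible, ] <- runif(length(eligible) * ncol(m)) <
      params$substitution_rate
    nh <- sum(hit)
    if (nh) {
      cur <- match(m[hit], DNA_BASES)
      m[hit] <- DNA_BASES[(cur - 1L + sample.int(3L, nh, replace = TRUE)) %% 4L + 1L]
      pos_hit <- row(hit)[hit]
      lab <- tapply(sprintf("%s:%d", pos_segment[pos_hit], pos_hit),
                    col(hit)[hit], paste, collapse = ",")
      labels[idx[as.integer(names(lab))]] <- as.character(lab)
      sequences[idx] <- apply_char_matrix(m)
    }
  } else {  # per_barcode: errors_per_read substitutions in one segment
    segs <- params$error_segments
    chosen <- segs[sample.int(length(segs), length(idx), replace = TRUE)]
    m <- seq_char_matrix(sequences[idx])
    lab <- character(length(idx))
    for (k in seq_along(idx)) {
      span <- which(pos_segment == chosen[[k]])
      pos <- span[sample.int(length(span), params$errors_per_read)]
      cur <- match(m[pos, k], DNA_BASES)
      m[pos, k] <- DNA_BASES[(cur - 1L +
                                sample.int(3L, length(pos), replace = TRUE)) %% 4L + 1L]
      lab[k] <- paste(sprintf("%s:%d", chosen[[k]], sort(pos)),
                      collapse = ",")
    }
    labels[idx] <- lab
    sequences[idx] <- apply_char_matrix(m)
  }
  list(sequences = sequences, labels = labels)
}

#' @noRd
apply_char_matrix <- function(m) {
  vapply(seq_len(ncol(m)), function(j) paste(m[, j], collapse = ""),
         character(1))
}

#' Write a simulated library to disk
#'
#' @param lib a `sim_library`.
#' @param outdir output directory.
#' @param demux_defaults `demux_config` recorded in the emitted config.
#' @return named list of written paths, invisibly.
#' @export
write_sim_library <- function(lib, outdir,
                              demux_defaults = demux_config(min_reads = 1L)) {
  stopifnot(inherits(lib, "sim_library"))
  dir.create(file.path(outdir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list(
    r1 = file.path(outdir, "r1.fastq.gz"),
    r2 = file.path(outdir, "r2.fastq.gz"),
    config = file.path(outdir, "config.cfg"),
    assignments = file.path(outdir, "assignments.tsv"),
    truth_reads = file.path(outdir, "truth", "reads.tsv"),
    truth_matrix = file.path(outdir, "truth"))
  write_fastq(lib$r1, paths$r1)
  write_fastq(lib$r2, paths$r2)
  wl_paths <- vapply(1:3, function(r) {
    p <- file.path(outdir, sprintf("whitelist_round%d.tsv", r))
    write_whitelist(lib$whitelists[[r]], p)
    p
  }, character(1))
  write_run_config(paths$config, lib$layout, wl_paths, demux_defaults)
  writeLines(c("read_id\tgene_id",
               paste(lib$assignments$read_id, lib$assignments$gene_id,
                     sep = "\t")),
             paths$assignments)
  tr <- lib$truth$reads
  writeLines(c(paste(names(tr), collapse = "\t"),
               do.call(paste, c(lapply(tr, function(x) {
                 ifelse(is.na(x), "", as.character(x))
               }), sep = "\t"))),
             paths$truth_reads)
  write_mtx(lib$truth$matrix, paths$truth_matrix)
  invisible(paths)
}

#' Evaluate pipeline output against simulation ground truth
#'
#' @param result a `demux_result` (after [filter_min_reads()] if a
#'   minimum-read threshold is part of the run).
#' @param matrix the produced gene-by-cell count matrix.
#' @param truth the `truth` element of a `sim_library` (list with
#'   `reads`, `matrix`, `cells`).
#' @return a `splitpool_evaluation`: read-assignment accuracy over
#'   genuine reads, the junk false-assignment rate, cell recovery
#'   (retained over truth cells), and matrix agreement (fraction of
#'   union non-zero entries identical, plus an exact-identity flag).
#' @export
evaluate_run <- function(result, matrix, truth) {
  stopifnot(inherits(result, "demux_result"))
  tr <- truth$reads
  genuine <- tr %>% filter(!.data$is_junk)
  if (nrow(genuine) && nrow(result$reads) &&
      !any(result$reads$cell_label %in% genuine$cell_label)) {
    abort("cell label namespaces of run and truth do not overlap",
          class = "splitpool_error")
  }
  assigned <- result$reads %>% select("original_id", "cell_label")
  joined <- genuine %>%
    left_join(assigned, by = c(read_id = "original_id"),
              suffix = c("_true", "_called"))
  read_accuracy <- if (nrow(joined)) {
    mean(!is.na(joined$cell_label_called) &
           joined$cell_label_called == joined$cell_label_true)
  } else {
    NA_real_
  }
  junk_ids <- tr$read_id[tr$is_junk]
  junk_pass_rate <- if (length(junk_ids)) {
    mean(junk_ids %in% result$reads$original_id)
  } else {
    0
  }
  retained <- result$retained_labels %||% unique(result$reads$cell_label)
  cell_recovery <- if (nrow(truth$cells)) {
    mean(truth$cells$cell_label %in% retained)
  } else {
    NA_real_
  }
  agreement <- matrix_agreement(matrix, truth$matrix)
  structure(list(read_accuracy = read_accuracy,
                 junk_pass_rate = junk_pass_rate,
                 cell_recovery = cell_recovery,
                 matrix_identical = agreement$identical,
                 matrix_entry_agreement = agreement$fraction,
                 n_genuine = nrow(genuine),
                 n_junk = length(junk_ids),
                 n_truth_cells = nrow(truth$cells),
                 n_retained_cells = length(retained)),
            class = "splitpool_evaluation")
}

#' Entry-wise agreement between two labelled sparse matrices
#'
#' @param a,b gene-by-cell matrices with dimnames.
#' @return list with `identical` (same dimnames, all entries equal) and
#'   `fraction` (identical entries over the union of non-zero positions).
#' @export
matrix_agreement <- function(a, b) {
  genes <- sort(union(rownames(a), rownames(b)))
  cells <- sort(union(colnames(a), colnames(b)))
  expand <- function(m) {
    out <- Matrix::Matrix(0, length(genes), length(cells), sparse = TRUE,
                          dimnames = list(genes, cells))
    if (nrow(m) && ncol(m)) out[rownames(m), colnames(m)] <- m
    out
  }
  ea <- expand(a)
  eb <- expand(b)
  nz <- Matrix::which(ea != 0 | eb != 0)
  frac <- if (length(nz)) {
    sum(ea[nz] == eb[nz]) / length(nz)
  } else {
    1
  }
  ident <- identical(dim(a), dim(b)) &&
    identical(dimnames(a), dimnames(b)) &&
    frac == 1
  list(identical = ident, fraction = frac)
}

#' @export
print.splitpool_evaluation <- function(x, ...) {
  cat("<splitpool_evaluation>\n")
  cat(sprintf("  read accuracy: %.4f (%d genuine reads)\n",
              x$read_accuracy, x$n_genuine))
  cat(sprintf("  junk pass rate: %.4f (%d junk reads)\n",
              x$junk_pass_rate, x$n_junk))
  cat(sprintf("  cell recovery: %.4f (%d / %d cells)\n",
              x$cell_recovery, x$n_retained_cells, x$n_truth_cells))
  cat(sprintf("  matrix agreement: %.4f%s\n", x$matrix_entry_agreement,
              if (x$matrix_identical) " (identical)" else ""))
  invisible(x)
}
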