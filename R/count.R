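# UMI counting: gene assignment join, UMI collapse, sparse matrix build,
# QC filtering and MatrixMarket I/O.

#' Join annotated reads with gene assignments
#'
#' The mapping/feature-assignment stage (aligner + feature counter) is
#' external to this package; its result is consumed as a read-to-gene
#' table keyed by the original read-1 identifier token. Reads without an
#' assignment are dropped and counted; the rest are aggregated into
#' molecule records by exact (cell, gene, UMI) triple.
#'
#' @param reads annotated reads: a `demux_result`, a tibble with columns
#'   `original_id`, `cell_label`, `umi` (as produced by
#'   [annotate_mate()]), or a path to an annotated FASTQ.
#' @param assignments two-column table `read_id`, `gene_id`: a data
#'   frame or a TSV path (gzip allowed, header auto-detected on the
#'   literal first line `read_id<TAB>gene_id`).
#' @param delimiter annotation delimiter, used when `reads` is a FASTQ
#'   path.
#' @return tibble of molecule records (`cell_label`, `gene_id`, `umi`,
#'   `read_count`), with attribute `unassigned` counting dropped reads.
#' @export
join_assignments <- function(reads, assignments, delimiter = "|") {
  if (inherits(reads, "demux_result")) {
    delimiter <- reads$config$delimiter
    reads <- reads$reads
  } else if (is.character(reads)) {
    fq <- read_fastq(reads)
    reads <- parse_annotation(fq$id, delimiter = delimiter)
  }
  stopifnot(all(c("original_id", "cell_label", "umi") %in% names(reads)))
  if (is.character(assignments)) {
    assignments <- read_assignments(assignments)
  }
  assignments <- as_tibble(assignments)
  stopifnot(all(c("read_id", "gene_id") %in% names(assignments)))
  dup <- unique(assignments$read_id[duplicated(assignments$read_id)])
  if (length(dup)) {
    abort(sprintf("duplicate read_id in assignment table: %s",
                  paste(head(dup, 5), collapse = ", ")),
          class = "splitpool_error")
  }
  joined <- reads %>%
    select("original_id", "cell_label", "umi") %>%
    inner_join(assignments, by = c(original_id = "read_id"))
  molecules <- joined %>%
    count(.data$cell_label, .data$gene_id, .data$umi, name = "read_count") %>%
    arrange(.data$cell_label, .data$gene_id, .data$umi)
  attr(molecules, "unassigned") <- nrow(reads) - nrow(joined)
  molecules
}

#' Read a read-to-gene assignment TSV
#'
#' @param path TSV with columns `read_id`, `gene_id`; `.gz` allowed.
#' @return tibble with columns `read_id`, `gene_id`.
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("assignment table not found: %s", path),
          class = "splitpool_error")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(lines[1L], "read_id\tgene_id")) {
    lines <- lines[-1L]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    abort(sprintf("assignment table %s: line %d lacks 2 fields", path,
                  bad[1L]), class = "splitpool_error")
  }
  tibble(read_id = vapply(parts, `[[`, character(1), 1L),
         gene_id = vapply(parts, `[[`, character(1), 2L))
}

#' Collapse UMIs into molecule counts per (cell, gene)
#'
#' `unique` counts the distinct UMI sequences in each (cell, gene)
#' group. `directional` applies the directional-adjacency network rule:
#' within a group, UMIs `u` and `v` are linked by a directed edge when
#' they differ at exactly one position and `read_count(u) >= 2 *
#' read_count(v) - 1`; each cluster grown from an unvisited UMI (visited
#' in decreasing read-count order, ties broken lexicographically) counts
#' as one molecule, absorbing sequencing-error satellites into their
#' parent UMI.
#'
#' @param molecules molecule records from [join_assignments()].
#' @param method `"directional"` (default) or `"unique"`.
#' @return tibble with columns `cell_label`, `gene_id`, `molecules`.
#' @export
collapse_umis <- function(molecules, method = c("directional", "unique")) {
  method <- match.arg(method)
  stopifnot(all(c("cell_label", "gene_id", "umi", "read_count") %in%
                  names(molecules)))
  if (!nrow(molecules)) {
    return(tibble(cell_label = character(), gene_id = character(),
                  molecules = integer()))
  }
  grouped <- molecules %>%
    group_by(.data$cell_label, .data$gene_id)
  if (method == "unique") {
    out <- grouped %>%
      summarise(molecules = n_distinct(.data$umi), .groups = "drop")
  } else {
    out <- grouped %>%
      summarise(molecules = directional_cluster_count(.data$umi,
                                                      .data$read_count),
                .groups = "drop")
  }
  arrange(out, .data$cell_label, .data$gene_id)
}

#' Directional-adjacency cluster count for one UMI group
#'
#' @param umis distinct UMI sequences of one (cell, gene) group.
#' @param counts read counts supporting each UMI.
#' @return number of molecule clusters (integer).
#' @export
directional_cluster_count <- function(umis, counts) {
  if (anyDuplicated(umis)) {
    agg <- rowsum(counts, umis)
    umis <- rownames(agg)
    counts <- as.vector(agg)
  }
  n <- length(umis)
  if (n == 0L) return(0L)
  if (length(unique(nchar(umis))) != 1L) {
    abort("UMIs of unequal length within a (cell, gene) group",
          class = "splitpool_error")
  }
  if (n == 1L) return(1L)
  d <- hamming_matrix(umis, umis)
  # directed adjacency: u -> v allowed when counts[u] >= 2*counts[v] - 1
  adj <- d == 1L & outer(counts, counts, function(u, v) u >= 2 * v - 1)
  ord <- order(-counts, umis)
  visited <- rep(FALSE, n)
  clusters <- 0L
  for (root in ord) {
    if (visited[root]) next
    clusters <- clusters + 1L
    queue <- root
    visited[root] <- TRUE
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[u, ] & !visited)
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  clusters
}

#' Build a sparse gene-by-cell count matrix
#'
#' Gene and cell name vectors are sorted lexicographically so the matrix
#' is invariant to input row order.
#'
#' @param collapsed tibble from [collapse_umis()] (columns `cell_label`,
#'   `gene_id`, `molecules`).
#' @return a `dgCMatrix` with genes as rows and cells as columns.
#' @export
build_matrix <- function(collapsed) {
  stopifnot(all(c("cell_label", "gene_id", "molecules") %in%
                  names(collapsed)))
  genes <- sort(unique(collapsed$gene_id))
  cells <- sort(unique(collapsed$cell_label))
  Matrix::sparseMatrix(
    i = match(collapsed$gene_id, genes),
    j = match(collapsed$cell_label, cells),
    x = as.numeric(collapsed$molecules),
    dims = c(length(genes), length(cells)),
    dimnames = list(genes, cells))
}

#' Apply single-nucleus QC filters to a count matrix
#'
#' Filters are applied in a fixed order: (1) cells with fewer than
#' `min_umis` total UMIs are removed; (2) genes detected in fewer than
#' `min_cells_per_gene` of the remaining cells are removed; (3) cells
#' whose mitochondrial UMI fraction exceeds `max_mito_frac`, or whose
#' total exceeds `max_umis`, are removed — fractions and totals computed
#' on the matrix entering step 3. All comparisons follow the stated
#' boundary semantics: a cell with exactly `min_umis` UMIs and a gene in
#' exactly `min_cells_per_gene` cells are retained; a cell at exactly
#' `max_mito_frac` or `max_umis` is retained.
#'
#' @param matrix gene-by-cell `dgCMatrix` (or coercible).
#' @param mito_genes character vector of mitochondrial gene identifiers
#'   (may be empty, disabling the mito rule).
#' @param min_umis minimum total UMIs per cell (default 500).
#' @param max_umis maximum total UMIs per cell (default 15000).
#' @param min_cells_per_gene minimum cells a gene must appear in
#'   (default 10).
#' @param max_mito_frac maximum mitochondrial UMI fraction (default 0.05).
#' @return list with `matrix` (filtered) and `report` (a `qc_report`).
#' @export
qc_filter <- function(matrix, mito_genes = character(),
                      min_umis = 500, max_umis = 15000,
                      min_cells_per_gene = 10, max_mito_frac = 0.05) {
  if (min_umis <= 0 || max_umis <= 0 || min_cells_per_gene <= 0 ||
      max_mito_frac <= 0) {
    abort("QC thresholds must be positive", class = "splitpool_config_error")
  }
  m <- as(matrix, "CsparseMatrix")
  dims_in <- dim(m)

  umis <- Matrix::colSums(m)
  keep_cells1 <- umis >= min_umis
  cells_removed_low_umi <- sum(!keep_cells1)
  m <- m[, keep_cells1, drop = FALSE]

  detected_in <- Matrix::rowSums(m > 0)
  keep_genes <- detected_in >= min_cells_per_gene
  genes_removed_low_cells <- sum(!keep_genes)
  m <- m[keep_genes, , drop = FALSE]

  umis3 <- Matrix::colSums(m)
  mito_rows <- rownames(m) %in% mito_genes
  mito_frac <- if (any(mito_rows)) {
    as.vector(Matrix::colSums(m[mito_rows, , drop = FALSE])) /
      pmax(umis3, 1)
  } else {
    rep(0, ncol(m))
  }
  high_mito <- mito_frac > max_mito_frac
  high_umi <- umis3 > max_umis
  keep_cells3 <- !(high_mito | high_umi)
  m <- m[, keep_cells3, drop = FALSE]

  report <- structure(list(
    thresholds = list(min_umis = min_umis, max_umis = max_umis,
                      min_cells_per_gene = min_cells_per_gene,
                      max_mito_frac = max_mito_frac),
    dims_in = dims_in,
    cells_removed_low_umi = as.integer(cells_removed_low_umi),
    genes_removed_low_cells = as.integer(genes_removed_low_cells),
    cells_removed_high_mito = as.integer(sum(high_mito)),
    cells_removed_high_umi = as.integer(sum(high_umi & !high_mito)),
    dims_out = dim(m)), class = "qc_report")
  list(matrix = m, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d x %d -> %d x %d (genes x cells)\n",
              x$dims_in[1], x$dims_in[2], x$dims_out[1], x$dims_out[2]))
  cat(sprintf("  cells removed: %d low-UMI, %d high-mito, %d high-UMI\n",
              x$cells_removed_low_umi, x$cells_removed_high_mito,
              x$cells_removed_high_umi))
  cat(sprintf("  genes removed: %d low-cell\n", x$genes_removed_low_cells))
  invisible(x)
}

#' Write a count matrix as a MatrixMarket trio
#'
#' Emits `matrix.mtx`, `features.tsv` (gene names) and `barcodes.tsv`
#' (cell labels), the de facto sparse count-matrix exchange layout.
#'
#' @param matrix gene-by-cell `dgCMatrix`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_mtx <- function(matrix, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(as(matrix, "CsparseMatrix"),
                  file.path(outdir, "matrix.mtx"))
  writeLines(rownames(matrix) %||% character(),
             file.path(outdir, "features.tsv"))
  writeLines(colnames(matrix) %||% character(),
             file.path(outdir, "barcodes.tsv"))
  invisible(outdir)
}

#' Read a MatrixMarket trio back into a sparse matrix
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return gene-by-cell `dgCMatrix`.
#' @export
read_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    abort(sprintf("missing matrix files: %s",
                  paste(missing_files, collapse = ", ")),
          class = "splitpool_error")
  }
  m <- tryCatch(Matrix::readMM(paths[[1L]]), error = function(e) {
    abort(sprintf("malformed MatrixMarket file %s: %s", paths[[1L]],
                  conditionMessage(e)), class = "splitpool_error")
  })
  genes <- readLines(paths[[2L]])
  cells <- readLines(paths[[3L]])
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    abort(sprintf(
      "matrix dimensions %d x %d do not match %d features / %d barcodes",
      nrow(m), ncol(m), length(genes), length(cells)),
      class = "splitpool_error")
  }
  m <- as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  m
}
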