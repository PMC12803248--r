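# Single-nucleus QC filter semantics and bookkeeping.

# A toy matrix builder: genes x cells from a named count list.
toy_matrix <- function(counts) {
  genes <- sort(unique(unlist(lapply(counts, names))))
  m <- matrix(0, nrow = length(genes), ncol = length(counts),
              dimnames = list(genes, names(counts)))
  for (cell in names(counts)) {
    m[names(counts[[cell]]), cell] <- counts[[cell]]
  }
  methods::as(m, "CsparseMatrix")
}

test_that("the low-UMI cell boundary is strict 'less than'", {
  m <- toy_matrix(list(keep = c(g1 = 500), drop = c(g1 = 499)))
  res <- qc_filter(m, min_cells_per_gene = 1)
  expect_equal(colnames(res$matrix), "keep")
  expect_equal(res$report$cells_removed_low_umi, 1L)
})

test_that("the gene detection boundary is strict 'fewer than'", {
  cells <- setNames(
    lapply(1:10, function(i) {
      if (i <= 9) c(g_in9 = 100, g_in10 = 400) else c(g_in10 = 500)
    }),
    paste0("cell", 1:10))
  m <- toy_matrix(cells)
  res <- qc_filter(m, min_umis = 1, min_cells_per_gene = 10)
  expect_equal(rownames(res$matrix), "g_in10")
  expect_equal(res$report$genes_removed_low_cells, 1L)

  res9 <- qc_filter(m, min_umis = 1, min_cells_per_gene = 9)
  expect_setequal(rownames(res9$matrix), c("g_in9", "g_in10"))
})

test_that("mito-fraction and high-UMI cell boundaries are inclusive", {
  m <- toy_matrix(list(
    mito_ok = c(mt1 = 50, g1 = 950),        # 5.0% mito: retained
    mito_hi = c(mt1 = 51, g1 = 949),        # 5.1% mito: removed
    umi_ok = c(g1 = 15000),                 # exactly 15000: retained
    umi_hi = c(g1 = 15001)))                # removed
  res <- qc_filter(m, mito_genes = "mt1", min_umis = 1,
                   min_cells_per_gene = 1)
  expect_setequal(colnames(res$matrix), c("mito_ok", "umi_ok"))
  expect_equal(res$report$cells_removed_high_mito, 1L)
  expect_equal(res$report$cells_removed_high_umi, 1L)
})

test_that("an empty mito gene set disables the mito rule", {
  m <- toy_matrix(list(c1 = c(mt1 = 900, g1 = 100)))
  res <- qc_filter(m, mito_genes = character(), min_umis = 1,
                   min_cells_per_gene = 1)
  expect_equal(res$report$cells_removed_high_mito, 0L)
  expect_equal(ncol(res$matrix), 1L)
})

test_that("removals reconcile with the dimension change on every axis", {
  set.seed(404)
  m <- Matrix::rsparsematrix(60, 80, density = 0.3,
                             rand.x = function(n) rpois(n, 40) + 1)
  dimnames(m) <- list(paste0("g", 1:60), paste0("c", 1:80))
  res <- qc_filter(m, mito_genes = paste0("g", 1:5),
                   min_umis = 300, max_umis = 900,
                   min_cells_per_gene = 20, max_mito_frac = 0.05)
  rep <- res$report
  expect_equal(rep$dims_in[1] - rep$genes_removed_low_cells,
               rep$dims_out[1])
  expect_equal(rep$dims_in[2] - rep$cells_removed_low_umi -
                 rep$cells_removed_high_mito - rep$cells_removed_high_umi,
               rep$dims_out[2])
  expect_true(all(dim(res$matrix) <= dim(m)))
})

test_that("non-positive thresholds are configuration errors", {
  m <- toy_matrix(list(c1 = c(g1 = 10)))
  expect_error(qc_filter(m, min_umis = 0), "positive")
  expect_error(qc_filter(m, max_mito_frac = -0.1), "positive")
})
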