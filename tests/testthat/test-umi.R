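# Gene-assignment join, UMI collapse, matrix construction and MTX I/O.

test_that("assignment join aggregates triples and counts unassigned reads", {
  reads <- tibble::tibble(
    original_id = c("r1", "r2", "r3", "r4"),
    cell_label = c("c1", "c1", "c1", "c2"),
    umi = c("AAAA", "AAAA", "CCCC", "AAAA"))
  assignments <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                                gene_id = c("g1", "g1", "g1"))
  mol <- join_assignments(reads, assignments)
  expect_equal(nrow(mol), 2)
  expect_equal(mol$read_count[mol$umi == "AAAA"], 2L)
  expect_equal(attr(mol, "unassigned"), 1L)

  empty <- join_assignments(reads,
                            tibble::tibble(read_id = character(),
                                           gene_id = character()))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "unassigned"), 4L)

  expect_error(
    join_assignments(reads, tibble::tibble(read_id = c("r1", "r1"),
                                           gene_id = c("g1", "g2"))),
    "duplicate read_id")
})

test_that("unique and directional collapse match the stated examples", {
  base <- tibble::tibble(cell_label = "c1", gene_id = "g1")
  dup <- dplyr::bind_rows(base, base) %>%
    dplyr::mutate(umi = "AAAAAAAAAA", read_count = 1L)
  expect_equal(collapse_umis(dup, "unique")$molecules, 1L)
  expect_equal(collapse_umis(dup, "directional")$molecules, 1L)

  pair <- dplyr::bind_rows(base, base) %>%
    dplyr::mutate(umi = c("AAAAAAAAAA", "AAAAAAAAAT"),
                  read_count = c(10L, 1L))
  expect_equal(collapse_umis(pair, "unique")$molecules, 2L)
  expect_equal(collapse_umis(pair, "directional")$molecules, 1L)

  # the parent rule is directional: equal counts do not merge
  even <- pair %>% dplyr::mutate(read_count = c(2L, 2L))
  expect_equal(collapse_umis(even, "directional")$molecules, 2L)

  none <- tibble::tibble(cell_label = character(), gene_id = character(),
                         umi = character(), read_count = integer())
  expect_equal(nrow(collapse_umis(none, "unique")), 0)

  ragged <- base %>% dplyr::mutate(umi = "AAAA", read_count = 1L) %>%
    dplyr::bind_rows(base %>% dplyr::mutate(umi = "AAAAA",
                                            read_count = 1L))
  expect_error(collapse_umis(ragged, "directional"), "unequal length")
})

test_that("directional collapse equals the reachability oracle and is
           bounded by unique counts", {
  set.seed(99)
  for (i in 1:200) {
    grp <- random_umi_group(sample(1:50, 1))
    got <- directional_cluster_count(grp$umi, grp$read_count)
    want <- bf_directional(grp$umi, grp$read_count)
    expect_equal(got, want)
    expect_lte(got, length(unique(grp$umi)))
  }
})

test_that("matrix construction is deterministic and order-invariant", {
  counts <- tibble::tibble(cell_label = c("c1", "c1"),
                           gene_id = c("g1", "g2"),
                           molecules = c(2L, 1L))
  m <- build_matrix(counts)
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(sum(m), 3)
  expect_equal(m["g1", "c1"], 2)

  shuffled <- counts[c(2, 1), ]
  expect_identical(build_matrix(shuffled), m)

  empty <- build_matrix(tibble::tibble(cell_label = character(),
                                       gene_id = character(),
                                       molecules = integer()))
  expect_equal(dim(empty), c(0L, 0L))
})

test_that("the MatrixMarket trio round-trips and rejects bad headers", {
  m <- Matrix::sparseMatrix(i = c(1, 3, 2), j = c(1, 2, 2),
                            x = c(5, 1, 2), dims = c(3, 2),
                            dimnames = list(c("g1", "g2", "g3"),
                                            c("c1", "c2")))
  dir <- withr::local_tempdir()
  write_mtx(m, dir)
  back <- read_mtx(dir)
  expect_equal(as.matrix(back), as.matrix(m))

  # empty matrix still writes a valid zero-entry file
  dir0 <- withr::local_tempdir()
  write_mtx(m[0, 0, drop = FALSE], dir0)
  expect_equal(dim(read_mtx(dir0)), c(0L, 0L))

  # an entry outside the declared dimensions is a format error
  dir_bad <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "3 1 7"), file.path(dir_bad, "matrix.mtx"))
  writeLines(c("g1", "g2"), file.path(dir_bad, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir_bad, "barcodes.tsv"))
  expect_error(read_mtx(dir_bad), "malformed|format|dimensions")

  # name files must match the declared dimensions
  dir_mis <- withr::local_tempdir()
  write_mtx(m, dir_mis)
  writeLines("g1", file.path(dir_mis, "features.tsv"))
  expect_error(read_mtx(dir_mis), "do not match")
})
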