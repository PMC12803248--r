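# Synthetic library generator: determinism, truth consistency, error modes.

test_that("identical parameters and seed give byte-identical libraries", {
  a <- quick_library(seed = 12, junk_fraction = 0.1,
                     substitution_rate = 0.01)
  b <- quick_library(seed = 12, junk_fraction = 0.1,
                     substitution_rate = 0.01)
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  expect_identical(a$truth$reads, b$truth$reads)
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_sim_library(a, dir_a)
  write_sim_library(b, dir_b)
  expect_identical(readLines(gzfile(file.path(dir_a, "r2.fastq.gz"))),
                   readLines(gzfile(file.path(dir_b, "r2.fastq.gz"))))
})

test_that("truth tables partition reads and match the FASTQ", {
  lib <- quick_library(seed = 13, junk_fraction = 0.2)
  tr <- lib$truth$reads
  expect_equal(nrow(tr), nrow(lib$r1))
  expect_equal(nrow(tr), nrow(lib$r2))
  expect_equal(tr$read_id, lib$r1$id)
  expect_true(all(xor(tr$is_junk, !is.na(tr$cell_label))))
  # truth matrix is the unique collapse of the genuine read triples
  manual <- tr %>%
    dplyr::filter(!is_junk) %>%
    dplyr::distinct(cell_label, gene_id, umi) %>%
    dplyr::count(cell_label, gene_id, name = "molecules")
  expect_identical(lib$truth$matrix, build_matrix(manual))
  expect_equal(sum(lib$truth$matrix), sum(manual$molecules))
})

test_that("error-free reads all parse at e = 0", {
  lib <- quick_library(seed = 14)
  calls <- extract_calls(lib$r2$sequence, lib$layout, lib$whitelists,
                         demux_config(edit_tolerance = 0))
  expect_true(all(calls$status == "pass"))
  expect_equal(calls$cell_label,
               lib$truth$reads$cell_label)
  expect_equal(calls$umi, lib$truth$reads$umi)
})

test_that("single-substitution reads are recoverable at e=1 but not e=0", {
  lib <- quick_library(seed = 15, error_mode = "per_barcode",
                       errors_per_read = 1, min_distance = 3)
  at_e1 <- extract_calls(lib$r2$sequence, lib$layout, lib$whitelists,
                         demux_config(edit_tolerance = 1))
  expect_true(all(at_e1$status == "pass"))
  expect_equal(at_e1$cell_label, lib$truth$reads$cell_label)
  at_e0 <- extract_calls(lib$r2$sequence, lib$layout, lib$whitelists,
                         demux_config(edit_tolerance = 0))
  expect_true(all(at_e0$status == "fail"))
  # the named failing round matches the segment the error was planted in
  seg <- sub(":.*", "", lib$truth$reads$injected_errors)
  expect_equal(at_e0$fail_reason, paste0("no_match_round",
                                         sub("bc", "", seg)))
})

test_that("requesting more cells than well combinations fails", {
  p <- sim_params(n_cells = 100, seed = 1, wells_per_round = c(4, 4, 4))
  expect_error(simulate_library(p), "well combinations")
})

test_that("junk counts are binomial draws recorded in the truth table", {
  lib <- quick_library(seed = 16, n_cells = 25, reads_per_cell = 40,
                       junk_fraction = 0.1)
  n_junk <- sum(lib$truth$reads$is_junk)
  expect_gt(n_junk, 0)
  res <- demultiplex(lib$r1, lib$r2, lib$whitelists, lib$layout,
                     config = demux_config(min_reads = 1))
  expect_equal(res$metrics$reads_total - res$metrics$reads_pass, n_junk)
})

test_that("a written library round-trips through the on-disk formats", {
  dir <- withr::local_tempdir()
  lib <- simulate_library(sim_params(n_cells = 8, n_genes = 6, seed = 17,
                                     wells_per_round = c(8, 8, 8),
                                     reads_per_cell = 10),
                          outdir = dir)
  run <- read_run_config(file.path(dir, "config.cfg"))
  expect_equal(as.data.frame(run$layout), as.data.frame(lib$layout))
  expect_equal(run$whitelists[[1]]$sequence, lib$whitelists[[1]]$sequence)
  truth <- read_truth(file.path(dir, "truth"))
  expect_equal(truth$reads$read_id, lib$truth$reads$read_id)
  expect_equal(truth$reads$is_junk, lib$truth$reads$is_junk)
  expect_equal(as.matrix(truth$matrix), as.matrix(lib$truth$matrix))
  asn <- read_assignments(file.path(dir, "assignments.tsv"))
  expect_equal(asn, lib$assignments)
  r2 <- read_fastq(file.path(dir, "r2.fastq.gz"))
  expect_equal(r2$sequence, lib$r2$sequence)
})
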