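# Whitelist loading, validation and distance bookkeeping.

test_that("whitelists round-trip through the TSV dialect losslessly", {
  set.seed(11)
  wl <- generate_whitelist(48, round_id = 1, min_distance = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_whitelist(wl, path)
  back <- read_whitelist(path, round_id = 1)
  expect_equal(back$well_id, wl$well_id)
  expect_equal(back$sequence, wl$sequence)
  expect_equal(attr(back, "min_distance"), attr(wl, "min_distance"))
  expect_equal(nrow(back), 48)
})

test_that("a header line is auto-detected and skipped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("well_id\tsequence", "A1\tAAAAAAAA", "A2\tCCCCCCCC"), path)
  wl <- read_whitelist(path, round_id = 2)
  expect_equal(nrow(wl), 2)
  expect_equal(wl$well_id, c("A1", "A2"))
})

test_that("validation rejects duplicates, ragged lengths and non-ACGT", {
  expect_error(
    barcode_whitelist(tibble::tibble(well_id = c("A1", "A2"),
                                     sequence = c("AAAAAAAA", "AAAAAAAA")),
                      round_id = 1),
    "duplicate sequences.*AAAAAAAA")
  expect_error(
    barcode_whitelist(tibble::tibble(well_id = c("A1", "A1"),
                                     sequence = c("AAAAAAAA", "CCCCCCCC")),
                      round_id = 1),
    "duplicate well_ids.*A1")
  expect_error(
    barcode_whitelist(tibble::tibble(well_id = c("A1", "A2"),
                                     sequence = c("AAAAAAAA", "CCCCCC")),
                      round_id = 1),
    "length")
  expect_error(
    barcode_whitelist(tibble::tibble(well_id = "A1", sequence = "AAAANAAA"),
                      round_id = 1),
    "non-ACGT")
})

test_that("a single-entry whitelist reports an undefined (infinite) distance", {
  wl <- barcode_whitelist(tibble::tibble(well_id = "A1",
                                         sequence = "AAAAAAAA"),
                          round_id = 1)
  expect_identical(attr(wl, "min_distance"), Inf)
})

test_that("near-identical entries trigger the ambiguity warning at e = 1", {
  expect_warning(
    wl <- barcode_whitelist(tibble::tibble(well_id = c("A1", "A2"),
                                           sequence = c("AAAAAAAA",
                                                        "AAAAAAAT")),
                            round_id = 1, warn_tolerance = 1),
    "may be ambiguous")
  expect_equal(attr(wl, "min_distance"), 1)
})

test_that("stored minimum distance matches brute-force all-pairs Hamming", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(2:96, 1)
    seqs <- unique(replicate(n, paste(sample(c("A", "C", "G", "T"), 8,
                                             replace = TRUE),
                                      collapse = "")))
    wl <- barcode_whitelist(
      tibble::tibble(well_id = paste0("W", seq_along(seqs)),
                     sequence = seqs),
      round_id = 1, warn_tolerance = 0)
    expect_equal(attr(wl, "min_distance"), bf_min_pairwise(seqs))
  }
})

test_that("generated whitelists honour the requested minimum distance", {
  set.seed(7)
  wl <- generate_whitelist(16, round_id = 2, min_distance = 5)
  expect_gte(attr(wl, "min_distance"), 5)
  expect_equal(nrow(wl), 16)
})
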