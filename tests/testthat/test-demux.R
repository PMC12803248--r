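# Barcode correction, position learning, extraction and annotation.

test_that("whitelist correction follows the distance/tie contract", {
  wl <- barcode_whitelist(tibble::tibble(well_id = c("A1", "B1"),
                                         sequence = c("AAAAAAAA",
                                                      "CCCCCCCC")),
                          round_id = 1, warn_tolerance = 0)
  exact <- correct_barcode("AAAAAAAA", wl, e = 1)
  expect_equal(exact$status, "match")
  expect_equal(exact$well_id, "A1")
  expect_equal(exact$distance, 0L)

  one_off <- correct_barcode("AAAAAAAT", wl, e = 1)
  expect_equal(one_off$status, "match")
  expect_equal(one_off$well_id, "A1")
  expect_equal(one_off$corrected, "AAAAAAAA")
  expect_equal(one_off$distance, 1L)

  expect_equal(correct_barcode("AATTAAAA", wl, e = 1)$status, "no_match")

  suppressWarnings(
    wl_close <- barcode_whitelist(tibble::tibble(
      well_id = c("A1", "A2"),
      sequence = c("AAAAAAAA", "AAAAAAAT")), round_id = 1))
  expect_equal(correct_barcode("AAAAAAAC", wl_close, e = 1)$status,
               "ambiguous")
})

test_that("'N' mismatches every base and UMIs are never corrected", {
  wl <- barcode_whitelist(tibble::tibble(well_id = "A1",
                                         sequence = "AAAAAAAA"),
                          round_id = 1, warn_tolerance = 0)
  expect_equal(correct_barcode("AAAAAAAN", wl, e = 1)$distance, 1L)
  expect_equal(correct_barcode("AAAAAANN", wl, e = 1)$status, "no_match")
})

test_that("correction agrees with exhaustive enumeration on random 8-mers", {
  set.seed(21)
  wl <- generate_whitelist(48, round_id = 1, min_distance = 1)
  obs <- replicate(10000, paste(sample(c("A", "C", "G", "T"), 8,
                                       replace = TRUE), collapse = ""))
  got <- correct_barcodes(obs, wl, e = 1)
  idx <- sample.int(length(obs), 400)  # spot-check against slow oracle
  for (i in idx) {
    want <- bf_correct(obs[i], wl, e = 1)
    expect_equal(got$status[i] == "match",
                 want$status == "match", info = obs[i])
    if (want$status == "match") {
      expect_equal(got$well_id[i], want$well_id, info = obs[i])
    } else {
      expect_equal(got$status[i], want$status, info = obs[i])
    }
  }
  # idempotence: corrected sequences re-correct to themselves at distance 0
  hits <- got[got$status == "match", ]
  again <- correct_barcodes(hits$corrected, wl, e = 1)
  expect_true(all(again$distance == 0L))
  expect_equal(again$well_id, hits$well_id)
})

test_that("positions are learned from planted linkers", {
  set.seed(31)
  layout <- fixture_layout()
  wl <- fixture_whitelists()
  reads <- vapply(1:200, function(i) {
    build_read2(sample(wl[[1]]$sequence, 1), sample(wl[[2]]$sequence, 1),
                sample(wl[[3]]$sequence, 1),
                paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                      collapse = ""))
  }, character(1))
  learned <- learn_positions(reads, layout)
  expect_equal(as.data.frame(learned), as.data.frame(layout))

  # 5% junk does not move the modal offset
  junk_at <- 1:10
  reads[junk_at] <- vapply(junk_at, function(i) {
    paste(sample(c("A", "C", "G", "T"), 94, replace = TRUE), collapse = "")
  }, character(1))
  learned2 <- learn_positions(reads, layout)
  expect_equal(as.data.frame(learned2), as.data.frame(layout))

  # absent linkers: learning must fail loudly
  noise <- vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), 94, replace = TRUE), collapse = "")
  }, character(1))
  expect_error(learn_positions(noise, layout), "layout learning failed")
})

test_that("extraction slices, corrects and fails with positional reasons", {
  layout <- fixture_layout()
  wl <- fixture_whitelists()
  umi <- "ACGTACGTAC"
  good <- build_read2("AAAAAAAA", "CGCGCGCG", "GGTTAACC", umi)
  call <- extract_call(good, layout, wl)
  expect_equal(call$status, "pass")
  expect_equal(call$cell_label, "A1.B2.C3")
  expect_equal(call$umi, umi)
  expect_true(all(c(call$bc1_distance, call$bc2_distance,
                    call$bc3_distance) == 0L))

  # one substitution inside bc2 is corrected at e = 1
  bad_bc2 <- build_read2("AAAAAAAA", "CGCGCGCT", "GGTTAACC", umi)
  call2 <- extract_call(bad_bc2, layout, wl)
  expect_equal(call2$status, "pass")
  expect_equal(call2$bc2_distance, 1L)
  expect_equal(call2$bc2_well, "B2")

  short <- extract_call(substr(good, 1, 40), layout, wl)
  expect_equal(short$fail_reason, "read_too_short")

  n_umi <- build_read2("AAAAAAAA", "CGCGCGCG", "GGTTAACC", "ACGTNCGTAC")
  expect_equal(extract_call(n_umi, layout, wl)$fail_reason, "umi_invalid")

  # round 3 precedes round 1 on the read, so it names the failure
  both_bad <- build_read2("AGGAAAAT", "CGCGCGCG", "GGCCAAGG", umi)
  expect_equal(extract_call(both_bad, layout, wl)$fail_reason,
               "no_match_round3")
})

test_that("mate annotation appends to the ID token and round-trips", {
  calls <- tibble::tibble(status = "pass", cell_label = "A1.B5.C9",
                          umi = "TTTTTTTTTT")
  r1 <- tibble::tibble(id = "readX 1:N:0:ACGT", sequence = "ACGT",
                       quality = "IIII")
  ann <- annotate_mate(r1, calls)
  expect_equal(ann$id, "readX|A1.B5.C9|TTTTTTTTTT")
  expect_equal(ann$sequence, "ACGT")
  parsed <- parse_annotation(ann$id)
  expect_equal(parsed$original_id, "readX")
  expect_equal(parsed$cell_label, "A1.B5.C9")
  expect_equal(parsed$umi, "TTTTTTTTTT")

  failing <- tibble::tibble(status = "fail", cell_label = NA, umi = NA)
  expect_error(annotate_mate(r1, failing), "passing calls")
})
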