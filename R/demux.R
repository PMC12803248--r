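# Core demultiplexing: position learning, barcode correction, extraction,
# mate annotation, binned/parallel streaming and metrics.

FAIL_REASONS <- c("read_too_short", "umi_invalid",
                  "no_match_round3", "ambiguous_round3",
                  "no_match_round2", "ambiguous_round2",
                  "no_match_round1", "ambiguous_round1")

#' Correct one observed barcode against a whitelist
#'
#' An exact whitelist hit is returned at distance 0. Otherwise the unique
#' whitelist entry at minimal distance `<= e` is returned; two or more
#' entries tied at the minimal qualifying distance yield `"ambiguous"`,
#' and no entry within `e` yields `"no_match"`. `N` (or any non-ACGT
#' symbol) counts as a mismatch against every base, so UMIs and barcodes
#' containing `N` can never match exactly.
#'
#' @param observed observed barcode sequence (single string).
#' @param whitelist a `barcode_whitelist`.
#' @param e maximum accepted distance.
#' @param metric `"hamming"` (substitution-only) or `"levenshtein"`.
#' @return list with elements `status` (`"match"`, `"no_match"` or
#'   `"ambiguous"`), `well_id`, `corrected`, `distance`.
#' @export
correct_barcode <- function(observed, whitelist, e = 1L,
                            metric = c("hamming", "levenshtein")) {
  res <- correct_barcodes(observed, whitelist, e = e,
                          metric = match.arg(metric))
  list(status = res$status[[1L]], well_id = res$well_id[[1L]],
       corrected = res$corrected[[1L]], distance = res$distance[[1L]])
}

#' Vectorised whitelist correction
#'
#' @param observed character vector of observed barcodes.
#' @inheritParams correct_barcode
#' @return tibble with columns `observed`, `status`, `well_id`,
#'   `corrected`, `distance`, aligned with `observed`.
#' @export
correct_barcodes <- function(observed, whitelist, e = 1L,
                             metric = c("hamming", "levenshtein")) {
  metric <- match.arg(metric)
  e <- as.integer(e)
  if (is.na(e) || e < 0L) {
    abort("e must be >= 0", class = "splitpool_config_error")
  }
  entries <- whitelist$sequence
  wells <- whitelist$well_id
  bl <- attr(whitelist, "barcode_length")
  n <- length(observed)
  status <- rep("no_match", n)
  well_id <- rep(NA_character_, n)
  corrected <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)

  hit <- match(observed, entries)
  exact <- !is.na(hit)
  status[exact] <- "match"
  well_id[exact] <- wells[hit[exact]]
  corrected[exact] <- entries[hit[exact]]
  distance[exact] <- 0L

  todo <- which(!exact & !is.na(observed))
  if (length(todo) && e > 0L) {
    uo <- unique(observed[todo])
    if (metric == "hamming") {
      usable <- uo[nchar(uo) == bl]
      d <- if (length(usable)) hamming_matrix(usable, entries) else
        matrix(integer(), 0L, length(entries))
      dmat <- matrix(NA_integer_, nrow = length(uo), ncol = length(entries))
      dmat[match(usable, uo), ] <- d
    } else {
      dmat <- utils::adist(uo, entries)
    }
    ustat <- rep("no_match", length(uo))
    uwell <- rep(NA_character_, length(uo))
    ucorr <- rep(NA_character_, length(uo))
    udist <- rep(NA_integer_, length(uo))
    for (i in seq_along(uo)) {
      di <- dmat[i, ]
      if (all(is.na(di))) next
      dmin <- min(di)
      if (dmin > e) next
      at_min <- which(di == dmin)
      if (length(at_min) == 1L) {
        ustat[i] <- "match"
        uwell[i] <- wells[at_min]
        ucorr[i] <- entries[at_min]
        udist[i] <- as.integer(dmin)
      } else {
        ustat[i] <- "ambiguous"
        udist[i] <- as.integer(dmin)
      }
    }
    m <- match(observed[todo], uo)
    status[todo] <- ustat[m]
    well_id[todo] <- uwell[m]
    corrected[todo] <- ucorr[m]
    distance[todo] <- udist[m]
  }
  tibble(observed = observed, status = status, well_id = well_id,
         corrected = corrected, distance = distance)
}

#' Learn barcode positions from static linker sequences
#'
#' Scans a sample of read-2 sequences for each linker (allowing up to
#' `linker_mismatch` mismatches), takes the modal 0-based start offset,
#' and re-derives the UMI and barcode offsets from the linker anchors:
#' the round-3 barcode and UMI sit immediately 5' of linker A, the
#' round-2 barcode immediately 3' of it, and the round-1 barcode
#' immediately 3' of linker B. Learning fails when a linker is found in
#' fewer than 10% of sampled reads, or when the modal offset accounts
#' for less than half of the matching reads.
#'
#' @param read2 character vector of read-2 sequences (a sample of up to
#'   `config$learning_sample_size` reads is used).
#' @param layout_template a `read_layout` providing segment lengths,
#'   order and linker sequences.
#' @param config a `demux_config`.
#' @return a `read_layout` with confirmed offsets.
#' @export
learn_positions <- function(read2, layout_template, config = demux_config()) {
  stopifnot(inherits(layout_template, "read_layout"))
  sample_reads <- head(read2, config$learning_sample_size)
  if (!length(sample_reads)) {
    abort("layout learning failed: no reads supplied",
          class = "splitpool_error")
  }
  subject <- Biostrings::DNAStringSet(sample_reads)
  anchor <- function(linker, label) {
    idx <- Biostrings::vmatchPattern(linker, subject,
                                     max.mismatch = config$linker_mismatch,
                                     fixed = TRUE)
    starts <- Biostrings::startIndex(idx)
    first <- vapply(starts, function(s) {
      if (length(s)) s[[1L]] else NA_integer_
    }, integer(1))
    frac_found <- mean(!is.na(first))
    if (frac_found < 0.10) {
      abort(sprintf(
        "layout learning failed: %s matched only %.1f%% of %d sampled reads",
        label, 100 * frac_found, length(first)),
        class = "splitpool_error")
    }
    tab <- table(first[!is.na(first)])
    modal <- as.integer(names(tab)[which.max(tab)])
    modal_frac <- max(tab) / sum(tab)
    if (modal_frac < 0.50) {
      hist_txt <- paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                        collapse = " ")
      abort(sprintf(
        "layout learning failed: modal %s offset %d covers only %.1f%% of matches (histogram 1-based start:count — %s)",
        label, modal - 1L, 100 * modal_frac, hist_txt),
        class = "splitpool_error")
    }
    modal - 1L  # 0-based
  }
  la <- anchor(attr(layout_template, "linker_a"), "linker_a")
  lb <- anchor(attr(layout_template, "linker_b"), "linker_b")
  bl <- attr(layout_template, "barcode_length")
  ul <- attr(layout_template, "umi_length")
  la_len <- nchar(attr(layout_template, "linker_a"))
  lb_len <- nchar(attr(layout_template, "linker_b"))
  bc3_start <- la - bl
  umi_start <- bc3_start - ul
  bc2_start <- la + la_len
  bc1_start <- lb + lb_len
  if (umi_start < 0L) {
    abort(sprintf(
      "layout learning failed: linker_a at offset %d leaves no room for UMI + bc3",
      la), class = "splitpool_error")
  }
  if (lb < bc2_start + bl) {
    abort(sprintf(
      "layout learning failed: linker_b offset %d overlaps the bc2 segment",
      lb), class = "splitpool_error")
  }
  segments <- tibble(
    segment = c("umi", "bc3", "linker_a", "bc2", "linker_b", "bc1"),
    start = c(umi_start, bc3_start, la, bc2_start, lb, bc1_start),
    length = c(ul, bl, la_len, bl, lb_len, bl))
  new_read_layout(segments, umi_length = ul, barcode_length = bl,
                  linker_a = attr(layout_template, "linker_a"),
                  linker_b = attr(layout_template, "linker_b"))
}

#' Extract and correct barcodes + UMI from read-2 sequences
#'
#' Each segment is sliced at its layout offset. Reads shorter than the
#' layout span fail with `read_too_short`; a UMI containing `N` (or any
#' non-ACGT symbol) fails with `umi_invalid`; barcode rounds are then
#' corrected in their order of appearance on read 2 (round 3, round 2,
#' round 1) and the first failing round sets `fail_reason`. UMIs are
#' taken verbatim and never corrected.
#'
#' @param read2 character vector of read-2 sequences.
#' @param layout a `read_layout` with confirmed offsets.
#' @param whitelists list of three `barcode_whitelist`s (rounds 1-3).
#' @param config a `demux_config`.
#' @return tibble with one row per read: `status` (`"pass"`/`"fail"`),
#'   `fail_reason`, `umi`, per-round observed/corrected sequences, wells
#'   and distances, and `cell_label` (`bc1.bc2.bc3`, plus the sublibrary
#'   tag when configured) for passing reads.
#' @export
extract_calls <- function(read2, layout, whitelists,
                          config = demux_config()) {
  stopifnot(inherits(layout, "read_layout"))
  wl <- order_whitelists(whitelists)
  validate_layout(layout, wl)
  check_config_vs_layout(config, layout)
  n <- length(read2)
  min_len <- attr(layout, "min_read2_length")
  fail_reason <- rep(NA_character_, n)
  too_short <- nchar(read2) < min_len
  fail_reason[too_short] <- "read_too_short"

  slice <- function(kind) {
    seg <- layout_segment(layout, kind)
    out <- rep(NA_character_, n)
    out[!too_short] <- substr(read2[!too_short], seg$start + 1L,
                              seg$start + seg$length)
    out
  }
  umi <- slice("umi")
  bad_umi <- !too_short & grepl("[^ACGT]", umi)
  fail_reason[is.na(fail_reason) & bad_umi] <- "umi_invalid"

  res <- list()
  for (r in 3:1) {
    obs <- slice(paste0("bc", r))
    corr <- correct_barcodes(obs, wl[[r]], e = config$edit_tolerance,
                             metric = config$edit_metric)
    res[[paste0("bc", r)]] <- corr
    reason <- ifelse(corr$status == "ambiguous",
                     paste0("ambiguous_round", r),
                     paste0("no_match_round", r))
    # rounds are visited in their order along read 2 (3, 2, 1), so the
    # first failing segment wins
    sel <- is.na(fail_reason) & !too_short & corr$status != "match"
    fail_reason[sel] <- reason[sel]
  }
  status <- ifelse(is.na(fail_reason), "pass", "fail")
  cell_label <- rep(NA_character_, n)
  ok <- status == "pass"
  if (any(ok)) {
    lab <- paste(res$bc1$well_id[ok], res$bc2$well_id[ok],
                 res$bc3$well_id[ok], sep = ".")
    if (!is.null(config$sublibrary)) {
      lab <- paste(lab, config$sublibrary, sep = ".")
    }
    cell_label[ok] <- lab
  }
  tibble(status = status,
         fail_reason = ifelse(is.na(fail_reason), "", fail_reason),
         umi = umi,
         bc1_observed = res$bc1$observed, bc1_well = res$bc1$well_id,
         bc1_corrected = res$bc1$corrected, bc1_distance = res$bc1$distance,
         bc2_observed = res$bc2$observed, bc2_well = res$bc2$well_id,
         bc2_corrected = res$bc2$corrected, bc2_distance = res$bc2$distance,
         bc3_observed = res$bc3$observed, bc3_well = res$bc3$well_id,
         bc3_corrected = res$bc3$corrected, bc3_distance = res$bc3$distance,
         cell_label = cell_label)
}

#' Extract one read's barcode call
#'
#' Single-read convenience wrapper around [extract_calls()].
#'
#' @param read2_sequence one read-2 sequence.
#' @inheritParams extract_calls
#' @return a one-row tibble (see [extract_calls()]).
#' @export
extract_call <- function(read2_sequence, layout, whitelists,
                         config = demux_config()) {
  extract_calls(read2_sequence, layout, whitelists, config)
}

#' Annotate read-1 mates with cell label and UMI
#'
#' Appends `<delimiter><cell_label><delimiter><umi>` to the first
#' whitespace-delimited token of each read-1 header. Sequences and
#' qualities are unchanged. All calls must be passing.
#'
#' @param read1 tibble with columns `id`, `sequence`, `quality`.
#' @param calls barcode calls aligned with `read1` rows (see
#'   [extract_calls()]); every row must have `status == "pass"`.
#' @param delimiter annotation separator (default `"|"`).
#' @return tibble with columns `original_id`, `id` (annotated),
#'   `sequence`, `quality`, `cell_label`, `umi`.
#' @export
annotate_mate <- function(read1, calls, delimiter = "|") {
  if (nrow(read1) != nrow(calls)) {
    abort("read1 and calls must have the same number of rows",
          class = "splitpool_error")
  }
  if (any(calls$status != "pass")) {
    abort("annotate_mate() requires passing calls only",
          class = "splitpool_error")
  }
  original_id <- id_token(read1$id)
  tibble(original_id = original_id,
         id = paste(original_id, calls$cell_label, calls$umi,
                    sep = delimiter),
         sequence = read1$sequence,
         quality = read1$quality,
         cell_label = calls$cell_label,
         umi = calls$umi)
}

#' Parse annotated read identifiers
#'
#' Inverse of the annotation applied by [annotate_mate()].
#'
#' @param ids character vector of annotated identifiers.
#' @param delimiter the separator used at annotation time.
#' @return tibble with columns `original_id`, `cell_label`, `umi`.
#' @export
parse_annotation <- function(ids, delimiter = "|") {
  parts <- strsplit(ids, delimiter, fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    abort(sprintf("identifier is not '%s'-annotated: %s", delimiter,
                  ids[bad[1L]]), class = "splitpool_error")
  }
  tibble(
    original_id = vapply(parts, function(p)
      paste(p[seq_len(length(p) - 2L)], collapse = delimiter), character(1)),
    cell_label = vapply(parts, function(p) p[[length(p) - 1L]], character(1)),
    umi = vapply(parts, function(p) p[[length(p)]], character(1)))
}

#' Demultiplex a paired-end split-pool library
#'
#' Streams mate-synchronised read-1/read-2 records through barcode
#' extraction in consecutive bins of `config$bin_size` pairs. Bins are
#' dispatched across up to `config$threads` workers; within-bin order is
#' preserved and bins are concatenated in index order, so the merged
#' output is identical for any thread count. Layout offsets are learned
#' from the data (via [learn_positions()]) unless `learn = FALSE`.
#'
#' @param r1,r2 FASTQ paths or read tibbles (from [read_fastq()]);
#'   record `k` of each is one mate pair.
#' @param whitelists list of three `barcode_whitelist`s.
#' @param layout a `read_layout` (template when `learn = TRUE`).
#' @param config a `demux_config`.
#' @param learn whether to confirm offsets from the data first.
#' @return a `demux_result`: list with `reads` (annotated read-1 tibble),
#'   `metrics` (a `demux_metrics`), `barcode_counts` (reads per cell
#'   label), the confirmed `layout` and the `config`.
#' @export
demultiplex <- function(r1, r2, whitelists, layout,
                        config = demux_config(), learn = TRUE) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf(
      "mate files are out of sync: read 1 has %d records, read 2 has %d (first discrepancy at record %d)",
      nrow(r1), nrow(r2), min(nrow(r1), nrow(r2)) + 1L),
      class = "splitpool_error")
  }
  wl <- order_whitelists(whitelists)
  check_config_vs_layout(config, layout)
  if (learn) {
    layout <- learn_positions(r2$sequence, layout, config)
  }
  validate_layout(layout, wl)

  n <- nrow(r1)
  bin_of <- if (n) ceiling(seq_len(n) / config$bin_size) else integer()
  bins <- if (n) split(seq_len(n), bin_of) else list()

  process_bin <- function(ix) {
    calls <- extract_calls(r2$sequence[ix], layout, wl, config)
    ok <- calls$status == "pass"
    annotated <- annotate_mate(r1[ix, ][ok, , drop = FALSE],
                               calls[ok, , drop = FALSE],
                               delimiter = config$delimiter)
    per_round <- vapply(1:3, function(r) {
      d <- calls[[paste0("bc", r, "_distance")]][ok]
      c(exact = sum(d == 0L), corrected = sum(d > 0L))
    }, numeric(2))
    list(annotated = annotated,
         fail = table(factor(calls$fail_reason[!ok], levels = FAIL_REASONS)),
         per_round = per_round,
         n = length(ix), n_pass = sum(ok))
  }
  workers <- max(1L, min(config$threads, length(bins)))
  results <- if (workers > 1L) {
    parallel::mclapply(bins, process_bin, mc.cores = workers)
  } else {
    lapply(bins, process_bin)
  }
  err <- vapply(results, inherits, logical(1), "try-error")
  if (any(err)) {
    abort(paste("bin processing failed:",
                as.character(results[[which(err)[1L]]])),
          class = "splitpool_error")
  }
  reads <- bind_rows(lapply(results, `[[`, "annotated"))
  fail_counts <- Reduce(`+`, lapply(results, `[[`, "fail"),
                        setNames(rep(0L, length(FAIL_REASONS)), FAIL_REASONS))
  per_round <- Reduce(`+`, lapply(results, `[[`, "per_round"),
                      matrix(0, 2, 3))
  barcode_counts <- if (nrow(reads)) {
    reads %>% count(.data$cell_label, name = "reads") %>%
      arrange(desc(.data$reads), .data$cell_label)
  } else {
    tibble(cell_label = character(), reads = integer())
  }
  metrics <- new_demux_metrics(
    reads_total = n,
    reads_pass = sum(vapply(results, `[[`, numeric(1), "n_pass")),
    fail_counts = setNames(as.integer(fail_counts), FAIL_REASONS),
    per_round = tibble(round = 1:3,
                       exact_match = as.integer(per_round["exact", ]),
                       corrected_match = as.integer(per_round["corrected", ])),
    barcode_counts = barcode_counts,
    min_reads = config$min_reads)
  structure(list(reads = reads, metrics = metrics,
                 barcode_counts = barcode_counts,
                 layout = layout, config = config),
            class = "demux_result")
}

#' @noRd
new_demux_metrics <- function(reads_total, reads_pass, fail_counts,
                              per_round, barcode_counts, min_reads) {
  passing <- barcode_counts$reads >= min_reads
  structure(list(
    reads_total = as.integer(reads_total),
    reads_pass = as.integer(reads_pass),
    reads_fail_by_reason = fail_counts,
    per_round = per_round,
    barcodes_detected = nrow(barcode_counts),
    min_reads = as.integer(min_reads),
    barcodes_passing_min_reads = sum(passing),
    reads_in_passing_barcodes = as.integer(sum(barcode_counts$reads[passing]))),
    class = "demux_metrics")
}

#' @export
print.demux_metrics <- function(x, ...) {
  cat(sprintf("<demux_metrics> %d reads: %d pass, %d fail\n",
              x$reads_total, x$reads_pass,
              x$reads_total - x$reads_pass))
  nz <- x$reads_fail_by_reason[x$reads_fail_by_reason > 0]
  if (length(nz)) {
    cat("  fail reasons:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  }
  cat(sprintf("  barcodes: %d detected, %d with >= %d reads (%d reads)\n",
              x$barcodes_detected, x$barcodes_passing_min_reads,
              x$min_reads, x$reads_in_passing_barcodes))
  invisible(x)
}

#' @export
print.demux_result <- function(x, ...) {
  cat("<demux_result>\n")
  print(x$metrics)
  invisible(x)
}

#' Apply the minimum-reads-per-barcode filter
#'
#' Cell barcodes supported by at least `m` passing reads are retained;
#' the rest are dropped, removing (by default) their reads from the
#' annotated stream. The threshold semantics are inclusive: a barcode
#' with exactly `m` reads is kept.
#'
#' @param x a `demux_result`, or a data frame of per-barcode counts with
#'   columns `cell_label` and `reads`.
#' @param m minimum reads per barcode; defaults to the run config's
#'   `min_reads` for a `demux_result`.
#' @param ... passed between methods.
#' @return for a `demux_result`: the result with `reads` restricted,
#'   `retained_labels` added and metrics updated; for a data frame: the
#'   retained rows.
#' @export
filter_min_reads <- function(x, m, ...) {
  UseMethod("filter_min_reads")
}

#' @rdname filter_min_reads
#' @export
filter_min_reads.demux_result <- function(x, m = x$config$min_reads, ...) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) {
    abort("m must be >= 1", class = "splitpool_config_error")
  }
  retained <- x$barcode_counts$cell_label[x$barcode_counts$reads >= m]
  mt <- x$metrics
  passing <- x$barcode_counts$reads >= m
  mt$min_reads <- m
  mt$barcodes_passing_min_reads <- sum(passing)
  mt$reads_in_passing_barcodes <- as.integer(sum(x$barcode_counts$reads[passing]))
  x$metrics <- mt
  x$retained_labels <- retained
  if (x$config$drop_filtered) {
    x$reads <- x$reads %>% filter(.data$cell_label %in% retained)
  }
  x
}

#' @rdname filter_min_reads
#' @export
filter_min_reads.data.frame <- function(x, m, ...) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) {
    abort("m must be >= 1", class = "splitpool_config_error")
  }
  stopifnot(all(c("cell_label", "reads") %in% names(x)))
  as_tibble(x) %>% filter(.data$reads >= m)
}

#' Write demultiplexing outputs to a directory
#'
#' Emits the annotated read-1 FASTQ, a metrics JSON and the per-barcode
#' read-count table.
#'
#' @param result a `demux_result`.
#' @param outdir output directory (created if missing).
#' @param gzip compress the FASTQ output.
#' @return the output directory, invisibly.
#' @export
write_demux <- function(result, outdir, gzip = TRUE) {
  stopifnot(inherits(result, "demux_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fq <- file.path(outdir, if (gzip) "annotated_r1.fastq.gz" else
    "annotated_r1.fastq")
  write_fastq(result$reads, fq)
  jsonlite::write_json(unclass_metrics(result$metrics),
                       file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c("cell_label\treads",
               paste(result$barcode_counts$cell_label,
                     result$barcode_counts$reads, sep = "\t")),
             file.path(outdir, "barcode_counts.tsv"))
  invisible(outdir)
}

#' @noRd
unclass_metrics <- function(m) {
  list(reads_total = m$reads_total,
       reads_pass = m$reads_pass,
       reads_fail_by_reason = as.list(m$reads_fail_by_reason),
       per_round = as.data.frame(m$per_round),
       barcodes_detected = m$barcodes_detected,
       min_reads = m$min_reads,
       barcodes_passing_min_reads = m$barcodes_passing_min_reads,
       reads_in_passing_barcodes = m$reads_in_passing_barcodes)
}
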