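# Barcode whitelists: one barcoding round's legal well -> sequence table.

#' Construct a barcode whitelist
#'
#' A whitelist is the set of legal barcode sequences for one split-pool
#' barcoding round, keyed by plate well. It is represented as a tibble with
#' columns `well_id` and `sequence` plus attributes recording the round,
#' the barcode length, and the minimum pairwise Hamming distance between
#' entries (used to judge whether error correction at a given tolerance is
#' guaranteed unambiguous).
#'
#' @param entries data frame with columns `well_id` and `sequence`.
#' @param round_id integer in 1..3 identifying the barcoding round.
#' @param barcode_length expected sequence length (default 8).
#' @param warn_tolerance edit tolerance `e` against which to check the
#'   unambiguity condition `min_distance >= 2e + 1`; a warning is emitted
#'   when the condition fails. Use `0` to disable the check.
#' @return a `barcode_whitelist` tibble.
#' @export
barcode_whitelist <- function(entries, round_id, barcode_length = 8L,
                              warn_tolerance = 1L) {
  entries <- as_tibble(entries)
  if (!all(c("well_id", "sequence") %in% names(entries))) {
    abort("whitelist needs columns 'well_id' and 'sequence'",
          class = "splitpool_error")
  }
  entries <- entries %>%
    mutate(well_id = as.character(.data$well_id),
           sequence = toupper(as.character(.data$sequence))) %>%
    select("well_id", "sequence")
  round_id <- as.integer(round_id)
  if (!round_id %in% 1:3) {
    abort("round_id must be 1, 2 or 3", class = "splitpool_error")
  }
  bad_len <- entries$sequence[nchar(entries$sequence) != barcode_length]
  if (length(bad_len)) {
    abort(sprintf("round %d: sequences not of length %d: %s", round_id,
                  barcode_length, paste(head(bad_len, 5), collapse = ", ")),
          class = "splitpool_error")
  }
  bad_chr <- entries$sequence[grepl("[^ACGT]", entries$sequence)]
  if (length(bad_chr)) {
    abort(sprintf("round %d: non-ACGT characters in: %s", round_id,
                  paste(head(bad_chr, 5), collapse = ", ")),
          class = "splitpool_error")
  }
  dup_seq <- unique(entries$sequence[duplicated(entries$sequence)])
  if (length(dup_seq)) {
    abort(sprintf("round %d: duplicate sequences: %s", round_id,
                  paste(head(dup_seq, 5), collapse = ", ")),
          class = "splitpool_error")
  }
  dup_well <- unique(entries$well_id[duplicated(entries$well_id)])
  if (length(dup_well)) {
    abort(sprintf("round %d: duplicate well_ids: %s", round_id,
                  paste(head(dup_well, 5), collapse = ", ")),
          class = "splitpool_error")
  }
  min_dist <- min_pairwise_hamming(entries$sequence)
  if (warn_tolerance > 0 && is.finite(min_dist) &&
      min_dist < 2L * warn_tolerance + 1L) {
    warn(sprintf(paste0("round %d: minimum pairwise Hamming distance is %d; ",
                        "correction at e = %d may be ambiguous ",
                        "(requires >= %d)"),
                 round_id, as.integer(min_dist), as.integer(warn_tolerance),
                 2L * as.integer(warn_tolerance) + 1L))
  }
  structure(entries,
            class = c("barcode_whitelist", class(entries)),
            round_id = round_id,
            barcode_length = as.integer(barcode_length),
            min_distance = min_dist)
}

#' Read a barcode whitelist from a two-column TSV
#'
#' The file holds `well_id<TAB>sequence` records, one per line. A header
#' line is optional and auto-detected: the first line is treated as a
#' header when its second field is not a pure A/C/G/T string.
#'
#' @inheritParams barcode_whitelist
#' @param path path to the TSV file.
#' @return a `barcode_whitelist` tibble.
#' @export
read_whitelist <- function(path, round_id, barcode_length = 8L,
                           warn_tolerance = 1L) {
  if (!file.exists(path)) {
    abort(sprintf("whitelist file not found: %s", path),
          class = "splitpool_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    abort(sprintf("whitelist file is empty: %s", path),
          class = "splitpool_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    abort(sprintf("whitelist %s: line %d has fewer than 2 tab-separated fields",
                  path, bad[1L]), class = "splitpool_error")
  }
  tab <- tibble(well_id = vapply(fields, `[[`, character(1), 1L),
                sequence = vapply(fields, `[[`, character(1), 2L))
  if (!grepl("^[ACGTacgt]+$", tab$sequence[1L])) {
    tab <- tab[-1L, , drop = FALSE]  # header line
  }
  barcode_whitelist(tab, round_id = round_id, barcode_length = barcode_length,
                    warn_tolerance = warn_tolerance)
}

#' Write a barcode whitelist as a two-column TSV
#'
#' @param whitelist a `barcode_whitelist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_whitelist <- function(whitelist, path) {
  writeLines(paste(whitelist$well_id, whitelist$sequence, sep = "\t"), path)
  invisible(path)
}

#' Generate a whitelist with a guaranteed minimum pairwise distance
#'
#' Samples random barcodes by seeded greedy rejection: a candidate is kept
#' only when its Hamming distance to every accepted barcode is at least
#' `min_distance`. Well identifiers follow the plate convention A1..H12.
#' Attainable set sizes shrink quickly as `min_distance` grows; the search
#' aborts after `max_tries` rejected candidates.
#'
#' @param n_wells number of barcodes to generate.
#' @param round_id barcoding round the whitelist is for.
#' @param barcode_length barcode length in nt (default 8).
#' @param min_distance required minimum pairwise Hamming distance.
#' @param max_tries candidate budget before giving up.
#' @return a `barcode_whitelist`.
#' @export
generate_whitelist <- function(n_wells, round_id, barcode_length = 8L,
                               min_distance = 3L, max_tries = 200000L) {
  wells <- paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, times = 8L))
  if (n_wells > length(wells)) {
    abort("n_wells must be <= 96 (one 96-well plate)",
          class = "splitpool_error")
  }
  picked <- character(0)
  pm <- NULL
  tries <- 0L
  while (length(picked) < n_wells && tries < max_tries) {
    tries <- tries + 1L
    cand_chr <- sample(DNA_BASES, barcode_length, replace = TRUE)
    cand <- paste(cand_chr, collapse = "")
    ok <- TRUE
    if (length(picked)) {
      d <- colSums(matrix(cand_chr, nrow = barcode_length,
                          ncol = length(picked)) != pm)
      ok <- all(d >= min_distance)
    }
    if (ok) {
      picked <- c(picked, cand)
      pm <- cbind(pm, cand_chr)
    }
  }
  if (length(picked) < n_wells) {
    abort(sprintf(paste0("could not find %d barcodes of length %d at minimum ",
                         "distance %d within %d tries"),
                  n_wells, barcode_length, min_distance, max_tries),
          class = "splitpool_error")
  }
  barcode_whitelist(tibble(well_id = wells[seq_len(n_wells)],
                           sequence = picked),
                    round_id = round_id, barcode_length = barcode_length,
                    warn_tolerance = 0L)
}

#' @export
print.barcode_whitelist <- function(x, ...) {
  cat(sprintf("<barcode_whitelist> round %d: %d wells, %d nt, min Hamming %s\n",
              attr(x, "round_id"), nrow(x), attr(x, "barcode_length"),
              format(attr(x, "min_distance"))))
  NextMethod()
}
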