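# Run configuration: the -n/-e/-m surface plus extraction details.

#' Demultiplexing run configuration
#'
#' Collects the tunable parameters of a demultiplexing run. The three
#' headline knobs mirror the tool's command-line flags: `threads` (-n),
#' `edit_tolerance` (-e, the per-barcode error budget) and `min_reads`
#' (-m, the minimum reads a cell barcode needs to be carried forward).
#'
#' @param threads number of parallel workers for bin processing.
#' @param edit_tolerance maximum per-barcode edit distance `e` accepted
#'   during whitelist correction (default 1).
#' @param min_reads minimum reads per cell barcode (default 200, the
#'   production-scale recommendation).
#' @param bin_size read pairs per processing bin (default 1e6). Bins
#'   bound memory use and define the units of parallel work; boundaries
#'   are record-index based, so output is identical for any thread count.
#' @param edit_metric `"hamming"` (substitution-only, default — segment
#'   offsets are fixed) or `"levenshtein"` (also counts indels, computed
#'   on the fixed-width segment slice).
#' @param linker_mismatch mismatches tolerated when anchoring linkers
#'   during position learning (default 1).
#' @param learning_sample_size reads sampled for position learning.
#' @param delimiter separator used when appending the cell label and UMI
#'   to read-1 identifiers; `"|"` never occurs in instrument read names.
#' @param sublibrary optional sublibrary tag appended to every cell label
#'   so labels stay unique when matrices from several Illumina-indexed
#'   sublibraries are merged.
#' @param drop_filtered whether `filter_min_reads()` removes reads of
#'   sub-threshold barcodes from the stream (default) or only records
#'   the retained label set.
#' @return a `demux_config` list.
#' @export
demux_config <- function(threads = 1L,
                         edit_tolerance = 1L,
                         min_reads = 200L,
                         bin_size = 1000000L,
                         edit_metric = c("hamming", "levenshtein"),
                         linker_mismatch = 1L,
                         learning_sample_size = 10000L,
                         delimiter = "|",
                         sublibrary = NULL,
                         drop_filtered = TRUE) {
  edit_metric <- match.arg(edit_metric)
  threads <- as.integer(threads)
  edit_tolerance <- as.integer(edit_tolerance)
  min_reads <- as.integer(min_reads)
  bin_size <- as.integer(bin_size)
  if (is.na(threads) || threads < 1L) {
    abort("threads must be a positive integer", class = "splitpool_config_error")
  }
  if (is.na(edit_tolerance) || edit_tolerance < 0L) {
    abort("edit_tolerance must be >= 0", class = "splitpool_config_error")
  }
  if (is.na(min_reads) || min_reads < 1L) {
    abort("min_reads must be >= 1", class = "splitpool_config_error")
  }
  if (is.na(bin_size) || bin_size < 1L) {
    abort("bin_size must be >= 1", class = "splitpool_config_error")
  }
  if (is.na(linker_mismatch) || linker_mismatch < 0L) {
    abort("linker_mismatch must be >= 0", class = "splitpool_config_error")
  }
  if (learning_sample_size < 1L) {
    abort("learning_sample_size must be >= 1", class = "splitpool_config_error")
  }
  if (!nzchar(delimiter)) {
    abort("delimiter must be non-empty", class = "splitpool_config_error")
  }
  structure(list(threads = threads,
                 edit_tolerance = edit_tolerance,
                 min_reads = min_reads,
                 bin_size = bin_size,
                 edit_metric = edit_metric,
                 linker_mismatch = as.integer(linker_mismatch),
                 learning_sample_size = as.integer(learning_sample_size),
                 delimiter = delimiter,
                 sublibrary = sublibrary,
                 drop_filtered = isTRUE(drop_filtered)),
            class = "demux_config")
}

#' Check config against a concrete barcode length
#' @noRd
check_config_vs_layout <- function(config, layout) {
  bl <- attr(layout, "barcode_length")
  if (config$edit_tolerance >= bl) {
    abort(sprintf("edit_tolerance (%d) must be < barcode length (%d)",
                  config$edit_tolerance, bl),
          class = "splitpool_config_error")
  }
  invisible(TRUE)
}

#' Write a run configuration file
#'
#' Serialises the layout, linker sequences, whitelist paths and run
#' parameters as `key = value` lines, one per key. The simulator emits
#' this file next to its FASTQ output so that demultiplexing always runs
#' against the exact layout the library was built with.
#'
#' @param path output path.
#' @param layout a `read_layout`.
#' @param whitelist_paths character vector of three whitelist TSV paths
#'   (rounds 1..3).
#' @param config a `demux_config`.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(path, layout, whitelist_paths, config) {
  stopifnot(inherits(layout, "read_layout"), length(whitelist_paths) == 3L)
  seg <- paste(sprintf("%s:%d:%d", layout$segment, layout$start,
                       layout$length), collapse = ",")
  lines <- c(
    sprintf("whitelist_round1 = %s", whitelist_paths[[1L]]),
    sprintf("whitelist_round2 = %s", whitelist_paths[[2L]]),
    sprintf("whitelist_round3 = %s", whitelist_paths[[3L]]),
    sprintf("linker_a = %s", attr(layout, "linker_a")),
    sprintf("linker_b = %s", attr(layout, "linker_b")),
    sprintf("umi_length = %d", attr(layout, "umi_length")),
    sprintf("barcode_length = %d", attr(layout, "barcode_length")),
    sprintf("segments = %s", seg),
    sprintf("threads = %d", config$threads),
    sprintf("edit_tolerance = %d", config$edit_tolerance),
    sprintf("min_reads = %d", config$min_reads),
    sprintf("bin_size = %d", config$bin_size),
    sprintf("edit_metric = %s", config$edit_metric),
    sprintf("linker_mismatch = %d", config$linker_mismatch),
    sprintf("learning_sample_size = %d", config$learning_sample_size),
    sprintf("delimiter = %s", config$delimiter))
  if (!is.null(config$sublibrary)) {
    lines <- c(lines, sprintf("sublibrary = %s", config$sublibrary))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' Parses the `key = value` format written by [write_run_config()].
#' Whitelist paths are resolved relative to the config file's directory
#' when not absolute.
#'
#' @param path path to the config file.
#' @return a list with elements `layout` (`read_layout`), `whitelists`
#'   (list of three `barcode_whitelist`s) and `config` (`demux_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "splitpool_config_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                        character(1)))
  opt <- setNames(as.list(vals), keys)
  need <- c("whitelist_round1", "whitelist_round2", "whitelist_round3",
            "linker_a", "linker_b", "segments")
  missing_keys <- setdiff(need, keys)
  if (length(missing_keys)) {
    abort(sprintf("config %s is missing keys: %s", path,
                  paste(missing_keys, collapse = ", ")),
          class = "splitpool_config_error")
  }
  base_dir <- dirname(path)
  resolve <- function(p) {
    if (file.exists(p) || grepl("^/", p)) p else file.path(base_dir, p)
  }
  seg_parts <- strsplit(strsplit(opt$segments, ",", fixed = TRUE)[[1L]],
                        ":", fixed = TRUE)
  segments <- tibble(
    segment = vapply(seg_parts, `[[`, character(1), 1L),
    start = as.integer(vapply(seg_parts, `[[`, character(1), 2L)),
    length = as.integer(vapply(seg_parts, `[[`, character(1), 3L)))
  layout <- new_read_layout(
    segments,
    umi_length = as.integer(opt$umi_length %||% layout_segment_len(segments, "umi")),
    barcode_length = as.integer(opt$barcode_length %||% layout_segment_len(segments, "bc1")),
    linker_a = opt$linker_a, linker_b = opt$linker_b)
  bl <- attr(layout, "barcode_length")
  whitelists <- lapply(1:3, function(r) {
    read_whitelist(resolve(opt[[paste0("whitelist_round", r)]]),
                   round_id = r, barcode_length = bl,
                   warn_tolerance = 0L)
  })
  config <- demux_config(
    threads = as.integer(opt$threads %||% 1L),
    edit_tolerance = as.integer(opt$edit_tolerance %||% 1L),
    min_reads = as.integer(opt$min_reads %||% 200L),
    bin_size = as.integer(opt$bin_size %||% 1000000L),
    edit_metric = opt$edit_metric %||% "hamming",
    linker_mismatch = as.integer(opt$linker_mismatch %||% 1L),
    learning_sample_size = as.integer(opt$learning_sample_size %||% 10000L),
    delimiter = opt$delimiter %||% "|",
    sublibrary = opt$sublibrary)
  list(layout = layout, whitelists = whitelists, config = config)
}

#' @noRd
layout_segment_len <- function(segments, kind) {
  segments$length[segments$segment == kind][[1L]]
}
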