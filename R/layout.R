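# Read-2 segment layout: where the UMI, barcodes and linkers sit.

SEGMENT_KINDS <- c("umi", "bc3", "linker_a", "bc2", "linker_b", "bc1")

#' Construct a read-2 layout
#'
#' Read 2 of a split-pool library carries, 5' to 3': the UMI, the round-3
#' barcode, a static linker, the round-2 barcode, a second static linker,
#' and the round-1 barcode. This function lays those segments out
#' contiguously from a given origin; offsets are 0-based and end-exclusive
#' throughout the package. With the defaults (10-nt UMI, 8-nt barcodes,
#' 30-nt linkers) the layout spans 94 nt, the read-2 length of the assay.
#'
#' @param linker_a,linker_b the static linker sequences flanking the
#'   round-2 barcode. They are instrument-run constants that anchor
#'   position learning; there is no universal default.
#' @param umi_length UMI length in nt (default 10).
#' @param barcode_length barcode length in nt (default 8).
#' @param origin 0-based offset of the first segment (default 0).
#' @return a `read_layout`: a tibble with columns `segment`, `start`,
#'   `length` (one row per segment, ascending `start`) and attributes
#'   `umi_length`, `barcode_length`, `linker_a`, `linker_b` and
#'   `min_read2_length` (the end of the last segment).
#' @export
splitpool_layout <- function(linker_a, linker_b, umi_length = 10L,
                             barcode_length = 8L, origin = 0L) {
  linker_a <- toupper(linker_a)
  linker_b <- toupper(linker_b)
  if (!nzchar(linker_a) || !nzchar(linker_b)) {
    abort("linker sequences must be non-empty", class = "splitpool_error")
  }
  if (grepl("[^ACGT]", linker_a) || grepl("[^ACGT]", linker_b)) {
    abort("linker sequences must be over A/C/G/T", class = "splitpool_error")
  }
  lens <- c(umi = as.integer(umi_length), bc3 = as.integer(barcode_length),
            linker_a = nchar(linker_a), bc2 = as.integer(barcode_length),
            linker_b = nchar(linker_b), bc1 = as.integer(barcode_length))
  starts <- as.integer(origin) + c(0L, cumsum(lens))[seq_along(lens)]
  segments <- tibble(segment = names(lens), start = starts,
                     length = unname(lens))
  new_read_layout(segments, umi_length = as.integer(umi_length),
                  barcode_length = as.integer(barcode_length),
                  linker_a = linker_a, linker_b = linker_b)
}

#' @noRd
new_read_layout <- function(segments, umi_length, barcode_length,
                            linker_a, linker_b) {
  segments <- arrange(as_tibble(segments), .data$start)
  if (!setequal(segments$segment, SEGMENT_KINDS)) {
    abort(sprintf("layout must contain exactly the segments: %s",
                  paste(SEGMENT_KINDS, collapse = ", ")),
          class = "splitpool_error")
  }
  ends <- segments$start + segments$length
  if (any(segments$start < 0L) || any(segments$length < 1L)) {
    abort("segment starts must be >= 0 and lengths >= 1",
          class = "splitpool_error")
  }
  if (any(segments$start[-1L] < ends[-nrow(segments)])) {
    abort("layout segments overlap or are not strictly ascending",
          class = "splitpool_error")
  }
  structure(segments,
            class = c("read_layout", class(segments)),
            umi_length = umi_length,
            barcode_length = barcode_length,
            linker_a = linker_a,
            linker_b = linker_b,
            min_read2_length = max(ends))
}

#' Segment lookup helper
#' @noRd
layout_segment <- function(layout, kind) {
  row <- layout[layout$segment == kind, ]
  list(start = row$start[[1L]], length = row$length[[1L]])
}

#' Validate a layout against the three round whitelists
#'
#' Checks that the three barcode segments have the length each round's
#' whitelist expects and that segments are non-overlapping and ascending
#' (enforced on construction, re-checked here). Problems raise errors;
#' on success a small validation report is returned.
#'
#' @param layout a `read_layout`.
#' @param whitelists list of three `barcode_whitelist` objects, rounds
#'   1, 2 and 3 (in any order; matched by their `round_id`).
#' @return a list with `valid = TRUE`, `min_read2_length` and the
#'   per-round barcode lengths, invisibly printable.
#' @export
validate_layout <- function(layout, whitelists) {
  stopifnot(inherits(layout, "read_layout"))
  wl <- order_whitelists(whitelists)
  for (r in 1:3) {
    seg <- layout_segment(layout, paste0("bc", r))
    expected <- attr(wl[[r]], "barcode_length")
    if (seg$length != expected) {
      abort(sprintf(
        "bc%d segment length %d does not match whitelist barcode length %d",
        r, seg$length, expected), class = "splitpool_error")
    }
  }
  list(valid = TRUE,
       min_read2_length = attr(layout, "min_read2_length"),
       barcode_lengths = vapply(wl, attr, integer(1), "barcode_length"))
}

#' Order a list of whitelists by round_id 1..3
#' @noRd
order_whitelists <- function(whitelists) {
  if (length(whitelists) != 3L) {
    abort("exactly three whitelists (rounds 1-3) are required",
          class = "splitpool_error")
  }
  rounds <- vapply(whitelists, attr, integer(1), "round_id")
  if (!setequal(rounds, 1:3)) {
    abort("whitelists must cover rounds 1, 2 and 3 exactly once",
          class = "splitpool_error")
  }
  whitelists[order(rounds)]
}

#' @export
print.read_layout <- function(x, ...) {
  cat(sprintf("<read_layout> %d segments, min read-2 length %d nt\n",
              nrow(x), attr(x, "min_read2_length")))
  NextMethod()
}
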