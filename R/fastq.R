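# FASTQ input/output as tibbles, backed by Biostrings.

#' Read a FASTQ file into a tibble
#'
#' Plain or gzip-compressed files are handled transparently. The full
#' header line (without the leading `@`) is kept in `id`; downstream
#' annotation operates on its first whitespace-delimited token.
#'
#' @param path path to a FASTQ file (`.fastq` or `.fastq.gz`).
#' @return tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTQ file not found: %s", path),
          class = "splitpool_error")
  }
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) {
      idx <- locate_bad_fastq_record(path)
      abort(sprintf("malformed FASTQ record at index %s in %s: %s",
                    ifelse(is.na(idx), "?", idx), path, conditionMessage(e)),
            class = "splitpool_error")
    })
  tibble(id = names(reads),
         sequence = unname(as.character(reads)),
         quality = unname(as.character(S4Vectors::mcols(reads)$qualities)))
}

# Find the 1-based index of the first structurally broken 4-line record.
#' @noRd
locate_bad_fastq_record <- function(path) {
  lines <- tryCatch(readLines(path), error = function(e) character())
  n_rec <- ceiling(length(lines) / 4L)
  for (k in seq_len(n_rec)) {
    chunk <- lines[(4L * (k - 1L) + 1L):min(4L * k, length(lines))]
    if (length(chunk) < 4L || !startsWith(chunk[1L], "@") ||
        !startsWith(chunk[3L], "+") ||
        nchar(chunk[2L]) != nchar(chunk[4L])) {
      return(k)
    }
  }
  NA_integer_
}

#' Write a tibble of reads as FASTQ
#'
#' @param reads tibble with columns `id`, `sequence`, `quality`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path))
  invisible(path)
}
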