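# Low-level sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Split equal-length sequences into a character matrix
#'
#' @param seqs character vector of equal-length strings.
#' @return matrix with `nchar(seqs[1])` rows and `length(seqs)` columns.
#' @noRd
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(character(), nrow = 0L, ncol = 0L))
  }
  len <- unique(nchar(seqs))
  if (length(len) != 1L) {
    abort("sequences must all have the same length", class = "splitpool_error")
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = len, ncol = length(seqs))
}

#' Pairwise Hamming distances between two sets of equal-length sequences
#'
#' 'N' (or any non-ACGT symbol) mismatches every base, including itself.
#'
#' @return integer matrix, `length(a)` rows by `length(b)` columns.
#' @noRd
hamming_matrix <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    return(matrix(integer(), nrow = length(a), ncol = length(b)))
  }
  if (any(nchar(a) != nchar(b[1L]))) {
    abort("sequences must have equal length for Hamming comparison",
          class = "splitpool_error")
  }
  ma <- seq_char_matrix(a)
  mb <- seq_char_matrix(b)
  # non-ACGT never matches anything, not even an identical symbol
  ma[!ma %in% DNA_BASES] <- NA_character_
  out <- matrix(0L, nrow = length(a), ncol = length(b))
  for (j in seq_along(b)) {
    out[, j] <- as.integer(colSums(ma != mb[, j] | is.na(ma)))
  }
  out
}

#' Minimum pairwise Hamming distance within a set of sequences
#'
#' @return `Inf` when fewer than two sequences are supplied.
#' @noRd
min_pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) {
    return(Inf)
  }
  m <- seq_char_matrix(seqs)
  best <- nrow(m)
  for (i in seq_len(n - 1L)) {
    d <- colSums(m[, (i + 1L):n, drop = FALSE] != m[, i])
    best <- min(best, d)
    if (best == 0L) break
  }
  as.numeric(best)
}

#' Random DNA strings
#' @noRd
random_dna <- function(n, len) {
  if (n == 0L) return(character())
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' First whitespace-delimited token of a read header
#' @noRd
id_token <- function(x) {
  sub("[ \t].*$", "", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
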