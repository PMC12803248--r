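# Shared fixtures and independent oracles for the test suite.

# Two fixed 30-nt linkers used wherever a deterministic layout is needed.
LINKER_A <- "GTGGCCGATGTTTCGCATCGGCGTACGACT"
LINKER_B <- "ATCCACGTGCTTGAGACTGTGGACACGACA"

fixture_layout <- function(umi_length = 10L, barcode_length = 8L) {
  splitpool_layout(linker_a = LINKER_A, linker_b = LINKER_B,
                   umi_length = umi_length, barcode_length = barcode_length)
}

# Small hand-written whitelists (min pairwise Hamming distance 8, 7, 6).
fixture_whitelists <- function() {
  list(
    barcode_whitelist(tibble::tibble(
      well_id = c("A1", "A2", "A3", "A4"),
      sequence = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT")),
      round_id = 1),
    barcode_whitelist(tibble::tibble(
      well_id = c("B1", "B2", "B3", "B4"),
      sequence = c("ACACACAC", "CGCGCGCG", "GTGTGTGT", "TATATATA")),
      round_id = 2),
    barcode_whitelist(tibble::tibble(
      well_id = c("C1", "C2", "C3", "C4"),
      sequence = c("AACCGGTT", "CCGGTTAA", "GGTTAACC", "TTAACCGG")),
      round_id = 3))
}

# Assemble a read-2 sequence from its parts under a layout.
build_read2 <- function(bc1, bc2, bc3, umi, layout = fixture_layout()) {
  paste0(umi, bc3, attr(layout, "linker_a"), bc2,
         attr(layout, "linker_b"), bc1)
}

# Independent brute-force oracles ------------------------------------------

bf_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

bf_min_pairwise <- function(seqs) {
  if (length(seqs) < 2) return(Inf)
  best <- Inf
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i < j) best <- min(best, bf_hamming(seqs[i], seqs[j]))
    }
  }
  best
}

# Plain enumeration of the correction rule; 'N' mismatches everything.
bf_correct <- function(obs, whitelist, e) {
  oc <- strsplit(obs, "")[[1]]
  d <- vapply(whitelist$sequence, function(s) {
    sc <- strsplit(s, "")[[1]]
    sum(oc != sc | !oc %in% c("A", "C", "G", "T"))
  }, numeric(1))
  dmin <- min(d)
  if (dmin > e) return(list(status = "no_match", well_id = NA_character_))
  hits <- which(d == dmin)
  if (length(hits) > 1) return(list(status = "ambiguous",
                                    well_id = NA_character_))
  list(status = "match", well_id = whitelist$well_id[hits],
       distance = dmin)
}

# Directional UMI clustering through igraph reachability: an independent
# route to the same rule used by directional_cluster_count().
bf_directional <- function(umis, counts) {
  n <- length(umis)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  chars <- strsplit(umis, "")
  edges <- integer(0)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u != v && sum(chars[[u]] != chars[[v]]) == 1 &&
          counts[u] >= 2 * counts[v] - 1) {
        edges <- c(edges, u, v)
      }
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = TRUE)
  ord <- order(-counts, umis)
  assigned <- rep(FALSE, n)
  clusters <- 0L
  for (root in ord) {
    if (assigned[root]) next
    clusters <- clusters + 1L
    # grow the cluster along directed edges, never crossing nodes already
    # captured by an earlier (higher-count) root
    todo <- root
    members <- root
    while (length(todo)) {
      u <- todo[[1]]
      todo <- todo[-1]
      nb <- setdiff(as.integer(igraph::neighbors(g, u, mode = "out")),
                    c(members, which(assigned)))
      members <- c(members, nb)
      todo <- c(todo, nb)
    }
    assigned[members] <- TRUE
  }
  clusters
}

# Random UMI group with enforced near-duplicates for directional testing.
random_umi_group <- function(size, umi_len = 10) {
  base_n <- max(1, ceiling(size / 2))
  umis <- character(0)
  pool <- replicate(base_n, paste(sample(c("A", "C", "G", "T"), umi_len,
                                         replace = TRUE), collapse = ""))
  umis <- pool
  while (length(umis) < size) {
    parent <- sample(umis, 1)
    pos <- sample.int(umi_len, 1)
    chars <- strsplit(parent, "")[[1]]
    chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
    umis <- c(umis, paste(chars, collapse = ""))
  }
  umis <- unique(umis)[seq_len(min(size, length(unique(umis))))]
  tibble::tibble(umi = umis,
                 read_count = sample.int(20, length(umis), replace = TRUE))
}

# Small simulated library with sensible test-scale defaults.
quick_library <- function(seed, n_cells = 20, reads_per_cell = 25,
                          n_genes = 10, wells = c(12, 12, 12), ...) {
  simulate_library(sim_params(n_cells = n_cells, n_genes = n_genes,
                              seed = seed, wells_per_round = wells,
                              reads_per_cell = reads_per_cell, ...))
}
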