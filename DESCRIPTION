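Package: splitpool
Title: Demultiplexing and UMI Counting for Split-Pool Barcoded Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for split-pool (SPLiT-seq style)
    combinatorial barcoding experiments: learns barcode positions in read 2
    from static linker sequences, extracts and error-corrects the three
    8-bp round barcodes against per-round whitelists, annotates read-1
    mates with the combined cell label and UMI, applies minimum-read
    filtering, collapses UMIs per cell and gene (unique or directional
    adjacency), builds sparse gene-by-cell count matrices, and applies
    standard single-nucleus quality-control filters. A seeded synthetic
    library simulator with per-read ground truth supports verification of
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    optparse,
    parallel,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
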