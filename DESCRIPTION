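Package: chseq
Title: Combinatorial Hybridization Single-Cell RNA-Seq Simulation,
    Demultiplexing and Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for split-pool combinatorial-hybridization single-cell
    RNA-seq libraries: a ground-truthed read simulator for two-species
    (barnyard) designs, multi-round barcode whitelist error correction and
    demultiplexing, k-mer based transcript assignment with UMI deduplication
    into sparse digital expression matrices, species-mixing quality control
    with the over-85-percent purity rule, and downstream statistics
    (permutation Spearman tests for time-associated genes, L1 centroid
    perturbation analysis, and pseudocell aggregation).
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
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
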