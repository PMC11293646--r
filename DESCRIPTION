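Package: plantmir
Title: Homology-Guided Prediction of Plant MicroRNA Precursors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An ab initio pipeline for discovering conserved plant
    microRNAs in genomic or transcriptomic sequence. Known mature
    miRNAs are aligned against the input with an exhaustive local
    aligner (or BLASTn), candidate windows are screened against
    protein-coding and rRNA/tRNA sets, folded into secondary
    structures, decomposed and scored against the accepted structural
    criteria for plant miRNA precursors (two-nucleotide 3' overhangs,
    bounded mismatch and bulge content, precursor and mature length
    limits), summarised as a 170-feature record, and discriminated
    from decoys by a dense SELU neural network. Includes generators
    for fully synthetic genomes, hairpins and feature tables with
    planted ground truth, and builders for matched positive and decoy
    training datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    generics,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
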