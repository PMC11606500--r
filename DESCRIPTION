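Package: tcrfirst
Title: TCR-First Analysis of Paired Single-Cell Expression and T Cell
    Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A TCR-first toolkit for paired single-cell gene expression and
    T cell receptor (TCR) sequencing data. Reads and quality-filters 10x-style
    contig tables and Matrix Market count matrices into a unified repertoire
    restricted to cells with both modalities; clusters CDR3 amino-acid
    junctions by Hamming-distance-1 hashing followed by Markov clustering;
    tests each clone for sequence-neighbor enrichment against a size- and
    composition-matched shuffled-junction background using the hypergeometric
    distribution with Bonferroni correction; annotates T cells by TCR gene
    rules (MAIT, gamma-delta, CD1b/c candidates) and rank-based
    marker-signature gating; and quantifies clonal dynamics across paired
    samples. Ships a toy amino-acid-level V(D)J recombination model for
    synthetic repertoires, Monte-Carlo and exact generation-probability
    estimation, and geometric-mean probability banding.
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
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
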