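Package: tpmda
Title: Tree-Path Attention Models for miRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts unobserved miRNA-disease associations from a sparse
    bipartite 0/1 association matrix. Instead of precomputed similarity
    matrices, each entity is represented by an association tree: a
    breadth-first tree rooted at that entity whose layers alternate between
    miRNAs and diseases, capturing indirect multi-hop relationships.
    Root-to-leaf tree-paths are encoded with multi-head scaled dot-product
    self-attention over learned node embeddings, the two entity encodings of
    a candidate pair are concatenated, and a fully connected neural network
    with three hidden layers scores the pair, trained end-to-end with Adam
    under balanced, fold-disjoint negative sampling and k-fold
    cross-validation. Includes a planted-block synthetic generator so the
    whole pipeline is testable offline, an association-matrix flatten mode
    for ablation, ROC/AUC utilities, and tidy/ggplot2 methods for all
    result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
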