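Package: bermad
Title: Batch Effect Removal for Single-Cell RNA-Seq with a Multi-Layer
    Adaptation Dual-Channel Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes batch effect from single-cell RNA sequencing data by
    training one deep autoencoder per batch (a dual-channel framework with
    shared architecture but unshared weights) and aligning similar cell
    clusters across batches with maximum-mean-discrepancy transfer losses
    computed at three intermediate layers of different dimensionality.
    Cross-batch cluster pairs are screened with a MetaNeighbor-style
    neighbour-voting AUROC and only pairs above a similarity threshold are
    matched, which guards batch-exclusive cell types against over-correction.
    Includes graph-based Louvain clustering, a splatter-like multi-batch
    count simulator with ground truth, and divergence, silhouette and ARI
    evaluation metrics for corrected embeddings.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    optparse,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
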