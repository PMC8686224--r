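Package: coembed
Title: Integration and Joint Dimensionality Reduction of Multimodal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates any number of datasets with different feature spaces
    (for example single-cell RNA-seq and ATAC-seq profiles of the same tissue)
    by recovering normalized manifold distances within each dataset and within
    shared feature spaces, assembling a single cross-dataset fuzzy neighborhood
    graph (the multigraph), and optimizing a joint low-dimensional embedding by
    weighted fuzzy cross-entropy. Includes graph- and embedding-based label
    transfer, benchmark metrics for integration quality (transfer accuracy,
    silhouette, alignment, structure preservation), and synthetic multimodal
    scenario generators for controlled evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RANN,
    RcppAnnoy,
    RSpectra,
    irlba,
    igraph,
    cluster,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    uwot,
    withr
Config/testthat/edition: 3
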