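Package: atheronet
Title: Single-Cell Contrast and Partial-Correlation Network Analysis of
    Atherosclerotic Plaque
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for contrasting single-cell RNA-seq profiles
    between atherosclerotic-core (AC) and proximal-adjacent (PA) arterial
    tissue: quality-control filtering and per-sample downsampling, graph-based
    cell partitioning with marker-driven cell-type assignment, marker-exclusion
    doublet filtering, normalized-effect differential expression with patient
    adjustment, pre-ranked gene-set enrichment, shrinkage partial-correlation
    (Gaussian graphical model) co-expression networks with Louvain modules,
    key-driver subnetwork extraction, and binarized biclustering of cell
    subpopulations. A synthetic-data generator with planted ground truth
    (negative-binomial Gaussian-copula counts, planted precision-matrix
    modules, planted differential effects, spiked cross-type doublets) makes
    every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
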