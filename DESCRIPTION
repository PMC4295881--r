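Package: omicfuse
Title: Multi-Omics Network Inference by Sparse Partial Correlations and
    Regularized Canonical Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a single global association network from several blocks of
    omics and clinical measurements on the same subjects. Within each block a
    sparse Gaussian graphical model (graphical lasso) estimates partial
    correlations; between each pair of blocks a ridge-regularized canonical
    correlation analysis scores cross-block variable pairs; each component
    network is calibrated so its edge count equals its node count before all
    networks are merged into one typed global graph. Downstream tools cluster
    the graph with a spin-glass simulated-annealing modularity optimizer, test
    modularity and within-cluster betweenness against degree-preserving
    rewiring nulls, extract hubs, compare clusters across networks with Fisher
    exact overlap tests, and run gene-set over-representation analysis. A
    synthetic multi-block cohort generator with known ground truth supports
    validation, and networks export to GraphML and GEXF for external layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    xml2,
    nortest,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
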