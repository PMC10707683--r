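Package: wmmnet
Title: Weighted Modularity Maximization for Stable and Hierarchical
    Community Detection in Weighted Networks
Version: 0.1.0
Authors@R:
    person("Wei", "Lin", email = "wlin.dev@posteo.net", role = c("aut", "cre"))
Description: Community detection for undirected weighted networks built
    around consensus-filtered modularity maximization. Provides a seeded
    Louvain-style optimizer of the (unnormalized) Newman-Girvan modularity
    with a resolution parameter, weighted modularity maximization (WMM:
    two rounds of co-assignment weight-matrix filtering of the adjacency
    matrix), a permutation-thresholded consensus baseline (robust MM), and
    a two-step hierarchical variant that subdivides communities only when
    a spatial-distance permutation test on node attributes supports the
    split. Ships partition-accuracy (normalized mutual information) and
    partition-stability (average node entropy with label matching)
    metrics, weighted planted-partition and attributed benchmark
    generators, and a group-level correlation-network construction stage
    for region-of-interest time series (Fisher z averaging and density
    thresholding).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
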