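Package: netbackbone
Title: Backbone Extraction for Weighted, Bipartite, and Unweighted Networks
Version: 1.0.0
Authors@R:
    person("Paul", "Reimer", email = "preimer.dev@posteo.net", role = c("aut", "cre"))
Description: Extracts the backbone - a sparse unweighted subgraph containing
    only the statistically or structurally important edges - from weighted
    networks, from weighted projections of bipartite networks, and from
    unweighted networks. Implements the global threshold, disparity filter,
    locally adaptive network sparsification and marginal likelihood filter
    for weighted networks; the stochastic and fixed degree sequence models
    (via the bipartite configuration model and fastball/curveball sampling)
    plus fixed row, column and fill nulls for bipartite projections; and a
    modular score/normalize/filter framework with ten named models (local
    and global sparsification, local degree, skeleton, Simmelian and
    quadrilateral Simmelian, Jaccard, meetmin, geometric, hypergeometric)
    for unweighted networks. Includes seeded toy-network generators, file
    input/output for common plain-text graph formats, and a command line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
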