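Package: brainstates
Title: Connectivity States, Transition Dynamics and Control Energy from
    Edge Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dynamic functional brain networks.
    Converts regional BOLD time series into framewise co-fluctuation
    (edge) time series, clusters pooled frames into recurrent
    connectivity states with city-block k-means (componentwise-median
    centroids), selects the number of states by an elbow criterion, and
    summarises per-subject state sequences as total transitions,
    fractional occupancy and directional transition probabilities. On a
    subject's structural connectome it computes network-control-theory
    minimum control energy for every framewise activity transition via
    the controllability Gramian, aggregates energies into a per-subject
    state-transition energy matrix referenced to healthy controls, and
    provides healthy-control-adjusted cognitive z-scoring with
    impairment classification plus covariate-adjusted group statistics
    (linear and Quade rank ANCOVA, partial correlations, Bonferroni).
    Includes a synthetic-cohort generator with planted Markov state
    sequences and ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    nortest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
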