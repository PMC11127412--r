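Package: boolss
Title: Continuous-Time Stochastic Simulation of Boolean Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates continuous-time Boolean signaling models with the
    Gillespie stochastic simulation algorithm under asynchronous update
    semantics. Parses and writes MaBoSS-style .bnd network and .cfg
    configuration files, compiles Boolean logic formulas into fast rate
    evaluators, aggregates trajectories into time-windowed state
    probabilities, final-state and fixed-point distributions over
    non-internal nodes (with interchangeable hashmap and dense-histogram
    backends and a deterministic reduction so results are independent of
    the worker partition), generates synthetic benchmark models with an
    analytically known mean trajectory length and no stable states, and
    verifies everything against an exact master-equation solver for small
    state spaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    compiler
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
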