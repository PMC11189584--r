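Package: hordyn
Title: Reconstruction of Higher-Order Interactions in Coupled Dynamical Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the structural connectivity of systems of coupled
    dynamical units -- both the pairwise adjacency matrix and the higher-order
    interaction tensors of a hypergraph or simplicial complex -- from sampled
    trajectories. Each node's interaction coefficients are estimated from a
    linear system built out of the sampled states and measured or
    finite-difference derivatives, solved by minimal-norm ordinary least
    squares, non-negative least squares, or the Signal Lasso. Includes forward
    simulators for generalized Lotka-Volterra dynamics on weighted directed
    hypergraphs and coupled Rossler oscillators on simplicial complexes, three
    finite-difference derivative estimators with exact index-range bookkeeping,
    discrepancy and reconstruction-error metrics, and sampling-budget sweep
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
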