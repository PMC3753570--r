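Package: boolfam
Title: Exhaustive Learning and Analysis of Boolean Logic Model Families
    for Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains Boolean logic models of signal transduction against
    perturbation phospho-proteomics data and, unlike stochastic search,
    characterizes the complete family of models compatible with the data.
    A prior knowledge network (Cytoscape SIF) is compressed and expanded
    into the hypergraph of all candidate AND gates; models (gate subsets,
    read as sum-of-products rules) are simulated to a quasi steady state
    and scored against MIDAS-format measurements by exact integer mean
    squared error. A complete branch-and-bound finds the lexicographic
    (MSE, size) optimum and enumerates every model within stated
    tolerances. The family is then analyzed structurally (gate
    frequencies, mutually inclusive/exclusive modules) and behaviorally
    (Global Truth Tables, core predictions, behavior clustering), and
    minimal sets of discriminating experiments are proposed by set cover.
    A synthetic-instance generator makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    ape,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
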