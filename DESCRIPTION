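Package: microaltruism
Title: Microbe-Induced Host Altruism: Analytic Recursions and Spatial Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the evolution of host altruistic behaviour induced by
    horizontally and vertically transmitted microbes. Provides the
    deterministic infinite-population recursion for a fully mixed host
    population with per-interaction horizontal microbe transmission,
    closed-form invasion conditions and critical benefit-cost thresholds, a
    finite-population Wright-Fisher style Monte-Carlo simulator used as an
    independent check of the recursion, and a lattice agent-based
    prisoner's-dilemma simulator with Nowak-May fittest-neighbour
    reproduction, imperfect vertical transmission and a genetic-allele
    control mode, together with drivers for threshold curves, parameter
    sweeps and invasion-probability experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
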