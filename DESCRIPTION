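Package: bitephylo
Title: Branch-Specific Rates, Evolutionary Tradeoffs and Heterochrony for
    Bite-Force Proxies on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the evolution of skull traits that proxy
    bite-force performance (retroarticular-process length and head width)
    on time-calibrated phylogenies that include fossil tips. Fits standard
    continuous-trait models (Brownian motion, Ornstein-Uhlenbeck,
    early-burst) by maximum likelihood with a pruning-algorithm core;
    estimates ancestral states and branch-specific rate multipliers under
    a multiple-variance Brownian-motion model by Markov chain Monte Carlo;
    places every branch in a signed two-trait rate space, fits a reduced
    major axis line, and classifies branches into six rate-tradeoff
    scenarios; and compares ten-stage ontogenetic and evolutionary
    trajectories of the log-trait ratio to detect inverted heterochrony.
    Includes simulators for time trees, (multi-rate) Brownian traits and
    biphasic allometric ontogenetic series used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
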