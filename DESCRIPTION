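Package: tracekin
Title: Single-Molecule Fluorescence Trace Idealization and Conformational Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule fluorescence intensity
    trajectories of membrane receptors observed by TIRF microscopy.
    Simulates state-switching traces from continuous-time Markov kinetic
    models with photobleaching, selects and normalizes dynamic traces,
    idealizes them with maximum-likelihood Gaussian hidden Markov models
    and Viterbi decoding, assigns consensus conformational states from
    two-dimensional transition density plots, fits multipeak Gaussian
    population histograms, and extracts per-transition dwell-time kinetics:
    mono/bi-exponential fits with reduced chi-squared model selection,
    amplitude-weighted rate constants, equilibrium rate-constant ratios
    with propagated uncertainty, and mean state occupancy times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    minpack.lm,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
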