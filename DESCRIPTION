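Package: rrddm
Title: Hierarchical Diffusion Modelling of Reward-Rate Optimal Decision Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the preregistered model-based analysis of speed-accuracy
    optimality in two-alternative forced-choice data. Implements the simple
    (no between-trial variability) diffusion decision model with exact
    first-passage-time densities, hierarchical Bayesian estimation by
    differential-evolution Markov chain Monte Carlo with migration,
    reward-rate-optimal decision thresholds, Savage-Dickey Bayes factors for
    distance-from-optimality hypotheses, preregistered exclusion rules,
    parameter-recovery and robustness harnesses, a synthetic-data generator
    emulating fixed-time and fixed-trial block designs, and a
    preregistration-skeleton renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
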