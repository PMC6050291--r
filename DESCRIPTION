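Package: lambdaswitch
Title: Production-State Kinetics of the Bistable Lambda Switch
Version: 0.1.0
Authors@R: person("Lambdaswitch", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of dual-reporter single-molecule
    gene-expression time traces for the mutually repressive CI/Cro pair of
    the bacteriophage lambda switch. Generates per-frame production-count
    traces over dividing cell lineages from a hidden Markov production
    process, quantifies molecules from localized fluorescent spots using a
    normalized-distance channel classifier, constructs the potential
    landscape U = -ln P over the bivariate production histogram with
    minimax barrier analysis, and fits multi-state hidden Markov models
    with Poisson count emissions (Baum-Welch, Viterbi) to recover
    production states, dwell times and transition time constants. Includes
    an exact stochastic (Gillespie) simulator of operator occupancy that
    illustrates how extra production states emerge in the non-adiabatic
    slow-binding regime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
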