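Package: coopstrat
Title: Multilevel Strategy Models for Direct and Generalized Reciprocity Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of repeated cooperation
    experiments. Simulates an iterated prisoner's dilemma with fixed pairs
    (direct reciprocity) and a sequential gift-giving game on five-player
    rings (generalized reciprocity), both with a perception-error channel
    on the displayed partner action. Fits multilevel Bernoulli-logit
    strategy models conditioning cooperation on a player's own and/or the
    partner's previous action by Hamiltonian Monte Carlo, compares models
    with WAIC and Akaike-type weights, summarizes group-level and
    individual-level posterior cooperation probabilities with compatibility
    intervals, and classifies participants into tit-for-tat-like,
    win-stay-lose-shift-like and non-cooperative behavioral types.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
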