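Package: crdelect
Title: Electoral Institutions in the Collective Risk Dilemma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact finite-population stochastic evolutionary dynamics for the
    collective risk dilemma (a risky threshold public goods game) extended with
    endogenously created, group-level electoral institutions that decide by
    majority vote whether to reward pro-social players or punish defectors.
    Provides the group payoff arithmetic for the full electoral model and its
    reward-only, punishment-only and institution-free restrictions,
    hypergeometric fitness, the selection-mutation Markov chain under the
    pairwise comparison (Fermi) rule, its stationary distribution via sparse
    eigensolvers, the gradient of selection, population-level observables
    (group achievement, critical risk, stationary abundances, incentive
    incidence, attractor detection), and seeded Monte Carlo simulation of
    evolutionary trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    tools,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
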