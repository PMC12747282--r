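Package: defenseEcology
Title: Eco-Evolutionary Modeling of Prokaryotic Antivirus Defense Strategies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models and statistics for the trade-off between immunity and
    programmed cell death (abortive infection) in prokaryotic antivirus
    defense. Implements a discrete-state chemostat model of host-virus
    dynamics with superinfection exclusion, immunity clearance and
    programmed-cell-death thresholds; fitness-landscape scans and
    optimal-strategy analysis; deterministic altruist-cheater competition; a
    stochastic structured-metapopulation (Simpson's paradox) simulator with
    migration and patch birth-death; maximum-likelihood power-law regression
    of genomic defense investment with Bayesian information criterion model
    comparison; abundance-stratified comparative statistics for metagenomic
    rank abundances; and synthetic-data generators with serialized ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    Matrix,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
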