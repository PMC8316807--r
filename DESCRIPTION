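Package: domstyle
Title: Dominance Style and Vocal Communication in Primate Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-level comparative analysis of how dominance style
    (the strictness with which a dominance hierarchy is enforced, from despotic
    to tolerant) predicts vocal communication in group-living primates. From raw
    behavioral observation tables the package computes modified David's scores
    and ordinal ranks, directional inconsistency of aggression, counteraggression
    and aggression-intensity profiles split into given and received tolerance,
    feeding-proximity tolerance, hourly vocal-bout rates with a 30-second bout
    chaining rule, and a species-level composite dominance-style index. At the
    individual level it fits Gaussian mixed models with nested group-within-species
    random intercepts by conjugate Gibbs sampling with inverse-Wishart variance
    priors, reporting posterior means, credible intervals, pMCMC and variance
    partitions. At the species level it fits phylogenetic generalized least
    squares with Pagel's lambda fixed, including taxon grafting onto a
    time-calibrated tree. A synthetic-study generator with known ground truth
    supports calibration and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
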