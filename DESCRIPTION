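Package: phasecouple
Title: Coupled Versus Uncoupled Phenotypic Evolution Across Life-History Phases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether phenotypic evolution is coupled or
    uncoupled between discrete life-history phases (e.g. tadpole and adult
    frogs) on a time-calibrated phylogeny. Provides character-state
    transformation distances and non-metric multidimensional scaling of
    categorical morphology matrices; maximum-likelihood fitting and AICc
    selection of time-varying birth-death diversification models; disparity
    through time and the morphological disparity index; reversible-jump
    MCMC for branch-specific Brownian-motion rate heterogeneity;
    multi-optimum Ornstein-Uhlenbeck regime-shift detection with forward
    addition and backward convergence collapse; randomization tests for
    concordance of regime-shift nodes and shift directions between phases;
    likelihood-ratio tests of correlated evolution for discrete character
    pairs; classification of phase-biased gene expression from FPKM tables;
    and seed-deterministic simulators for all of these inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    phangorn,
    vegan,
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
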