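Package: nemobo
Title: Multiobjective Bayesian Self-Optimization of Chemical Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-loop multiobjective Bayesian optimization of chemical
    reactions over mixed continuous and descriptor-featurized discrete
    variables, in the style of nomadic exploratory multiobjective
    optimization (NEMO). Provides a surrogate-model zoo with
    cross-validated model selection, joint batch expected-hypervolume
    improvement (EHVI) acquisition with local refinement, Latin hypercube
    designs stratified over a discrete solvent choice, an a-priori
    chemistry layer (sigma-moment solvent featurization and filtering,
    solubility-clamped bounds, Beer-Lambert transparency checks, an
    analytic reaction-cost objective), pool-based benchmarking,
    permutation feature importance and partial dependence, and a
    synthetic photoredox-yield simulator so the full loop runs without a
    laboratory.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
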