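Package: transportsim
Title: Simulation Study of Adjustment-Set Choice When Transporting
    Treatment Effects to External Target Populations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Monte Carlo evaluation of how the composition of a
    covariate adjustment set affects the bias and precision of treatment
    effects transported from a randomized trial to an external target
    population.  Implements a configurable data-generating process with
    binary or continuous covariates and a linear probability outcome
    model, two transport estimators (inverse odds weighting with Hajek
    normalization, and treatment-stratified outcome-model
    standardization), closed-form true effects, a paired replicate
    simulation engine, and tabular reporting of mean estimates, empirical
    standard errors, and relative precision against declared referent
    adjustment sets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
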