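Package: moranselect
Title: Moran-Model Estimation of Selection Coefficients for Expanding
    Mutant Clones
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the expansion of a selectively advantaged
    mutant clone in a constant-size stem-cell pool as a Moran process with
    directional selection and recurrent mutation. Provides exact chain
    quantities (transition probabilities and rates, fixation probability,
    fixation-time asymptotics), an exact Gillespie simulator of the
    time-continuous chain with ensemble summaries, the closed-form
    mean-field frequency curve, and a two-time-point estimator of the
    selection coefficient with its mutation-selection trade-off curve.
    Ships a curated table of published CSF3R-mutant clone frequencies from
    severe congenital neutropenia patients progressing to MDS/AML, routines
    that reproduce the published per-patient estimates, and a synthetic-data
    generator for parameter-recovery validation of the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
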