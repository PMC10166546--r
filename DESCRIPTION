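Package: vfarchetypes
Title: Archetypal Analysis of Longitudinal 24-2 Visual Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits archetypal-analysis models to 24-2 visual-field total-deviation
    data by alternating constrained least squares with simplex constraints,
    selects the number of archetypes by patient-grouped ten-fold cross-validated
    residual error, and decomposes individual fields into percent weights on a
    frozen archetype basis. Provides the clinical summaries used for papilledema
    cohorts: per-archetype relative weights and average total deviation,
    mean-deviation severity strata, prognosis splits on the normal-archetype
    percent weight, and residual-deficit detection in fields with normal mean
    deviation. Includes a synthetic longitudinal cohort generator with known
    archetypal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
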