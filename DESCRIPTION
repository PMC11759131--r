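Package: cmforest
Title: Conditional-Inference Forest Analysis of Child Maltreatment
    Characteristics and Adult Physical Multimorbidity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying which characteristics of retrospectively
    reported child maltreatment (subtype, timing, duration, frequency,
    severity, multiplicity) are most strongly associated with a count of
    physical diseases in adulthood.  Provides a synthetic survey-cohort
    generator with configurable ground truth, ICAST-R-style feature
    derivation, a from-scratch conditional-inference regression forest
    with marginal and conditional permutation variable importance,
    cross-validated importance estimation with an outcome-reshuffling
    permutation null, importance contrasts, stratified descriptive tests,
    and linear sensitivity models with age-group interactions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
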