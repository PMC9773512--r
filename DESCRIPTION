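Package: doqed
Title: Causal Effect Screening and Quantification for Observational Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for establishing and quantifying causal effects of a
    binary exposure on a binary outcome in observational discrete cohorts.
    Screens for a causal relationship by matched-pair quasi-experimental
    comparison with a sign test, identifies the interventional estimand
    P(Y|do(X)) on a user-supplied causal graph via the three do-calculus
    rewrite rules (back-door, front-door, instrumental-variable patterns),
    and evaluates it by plug-in estimation from empirical frequency tables.
    Ships a discrete structural-causal-model simulator with exact
    interventional ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
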