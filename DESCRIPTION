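Package: hfmdgbt
Title: Gradient Boosted Tree Risk Analysis for Severe Hand-Foot-Mouth Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying clinical and MRI predictors of severe
    hand-foot-mouth disease (HFMD) in children with gradient boosted
    regression trees. Implements a from-scratch boosting core for binary
    outcomes (Bernoulli deviance) that records per-split squared-error
    improvements, Friedman relative importance normalised to a maximum of
    100, partial dependence and the Friedman-Popescu pairwise H-statistic,
    outcome-permutation significance tests and percentile-bootstrap
    confidence intervals, stratified 10-fold cross-validation with optional
    majority-class down-sampling, and a calibrated synthetic cohort
    generator with an optional logistic data-generating process for planted
    main effects and interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
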