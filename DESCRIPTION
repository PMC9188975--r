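Package: brainagekit
Title: Evaluation Machinery for Brain-Age Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the performance metrics of age-prediction
    ("brain-age") models -- Pearson's r, R-squared, RMSE and MAE -- depend on
    cohort age range, sample size, prediction variance, mean-age differences
    between training and test sets, and age-bias correction. Provides a
    synthetic cohort generator with linear-in-age feature signal, a
    cross-validated prediction harness with a pluggable regressor contract,
    the linear and slope-division (Cole-style) age-bias correction family
    with their algebraic equivalences, performance metrics with bootstrap
    uncertainties, per-individual prediction uncertainty via training-set
    bootstrapping, and orchestrated experiment designs that reproduce the
    range-restriction, sample-size and label-shuffling phenomena on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
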