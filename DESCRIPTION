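Package: takeovr
Title: Predicting Critical Take-Over Success from Individual Ability
    Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for modelling whether a driver regains control of a
    conditionally automated vehicle without a collision, from a battery
    of visuo-attentional, executive and biographical ability measures.
    Implements partial least squares logistic regression (PLS-GLR) for a
    binary outcome, leave-one-out model evaluation with a Minimax
    (minimise the larger of false positives and false negatives)
    selection rule, exhaustive predictor-subset search, permutation
    robustness analysis, univariate group comparisons, per-test scoring
    of trial-level records (including stop-signal reaction time by the
    integration method), and a seeded synthetic-cohort generator that
    emulates the abilities-matrix structure the pipeline expects.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
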