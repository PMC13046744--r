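Package: rhythmage
Title: Rest-Activity Rhythms, Biological Age, and Inflammation-Mediated Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline linking wrist-accelerometry
    rest-activity rhythms to biological aging and systemic inflammation.
    Extracts cosinor, nonparametric circadian, physical-activity,
    fractal-complexity (DFA), functional-PCA, and sleep features from
    minute-level ENMO traces; estimates a Gompertz proportional-hazards
    biological age (CosinorAge) by equating five-year mortality risks;
    classifies accelerated aging with MRMR feature selection and Shapley
    attributions; models the systemic immune-inflammation index (SII) with
    quartile-coded generalized linear models; and quantifies the proportion
    of mortality risk mediated through inflammation with weighting-based
    natural-effects survival models and bootstrap confidence intervals.
    A seeded synthetic-cohort generator with known ground truth makes every
    stage testable without access to restricted cohort data.
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
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    randomForest,
    rpart,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
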