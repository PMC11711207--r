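Package: mindcpm
Title: Connectome-Based Predictive Modeling of Trait Mindfulness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting trait mindfulness (Five Facet Mindfulness
    Questionnaire scores) from resting-state functional connectomes with
    connectome-based predictive modeling (CPM). Covers questionnaire scoring,
    head-motion quality control, Fisher-z connectome construction, edge-wise
    correlation screening into positive and negative networks, network-strength
    linear models with leave-one-out or k-fold cross-validation, permutation
    inference, frozen-model external validation, mask overlap and split-half
    stability analyses, network anatomy summaries, and a seeded multi-site
    synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
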