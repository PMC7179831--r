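Package: triadml
Title: Lab-Event-Lab Triplet Mining and Clinician-Informed Feature
    Engineering for ICU Mortality Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines lab-event-lab triplets (a laboratory value captured
    immediately before and after a clinical event such as a prescription
    or procedure) from longitudinal intensive-care data, scores each
    triplet's association with in-hospital mortality by mutual
    information on a 2x3 outcome-by-direction contingency table, and
    aggregates per-laboratory composite discriminative scores used to
    rank and filter features. Builds the nested design matrices (lab
    slot statistics over the first 48 hours, plus demographics, event
    indicators, and event-masked lab duplicates) and runs a model
    complexity/accuracy/fidelity experiment grid over logistic
    regression, gradient boosting, neural network and weighted
    k-nearest-neighbour classifiers. Includes a synthetic ICU cohort
    generator with plantable lab-event-lab mortality associations so
    the whole pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    glmnet,
    nnet,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
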