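Package: dsindex
Title: Disease State Index Models for Dementia and Neuropathology Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Disease State Index (DSI), a supervised classifier
    that maps heterogeneous clinical measurements to a 0-1 similarity-to-cases
    score via per-factor fitness curves weighted by Youden-index relevance and
    aggregated recursively through a concept-group hierarchy.  Provides the
    surrounding analysis pipeline used in oldest-old dementia cohort studies:
    univariate factor screening (Mann-Whitney U and chi-square tests), repeated
    k-fold cross-validated AUC with sensitivity and specificity at a fixed
    index cutoff, derivation of binary neuropathological outcomes (including
    the NIA-AA Braak-by-CERAD likelihood dichotomization), a centered
    principal-component stage relating pathology patterns to dementia, and a
    synthetic-cohort generator emulating the baseline structure of an
    85+ population study so that every stage is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
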