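Package: ocsnlp
Title: Rule-Based Detection of Obsessive-Compulsive Symptom Mentions in
    Clinical Free Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A rules-based natural language processing pipeline for finding
    mentions of obsessive-compulsive symptoms (OCS) in psychiatric clinical
    notes. Provides wildcard-stem keyword lexicons with per-pattern
    exceptions, deterministic sentence segmentation, keyword-anchored
    context windows, five component detectors (obsessions, compulsions,
    OCD, hoarding, rituals) combined under a shared exclusion engine
    (questionnaire/form text, negation, non-patient experiencers, hedges,
    self-diagnosis), instance- and document-level classification, an
    evaluation layer (precision/recall with exact binomial confidence
    intervals, Cohen's kappa), and a seeded generator of labelled
    synthetic pseudo-clinical notes so every rule can be exercised without
    access to restricted health-record data.
License: MIT
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
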