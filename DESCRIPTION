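Package: switchscope
Title: Treatment-Switching Cohorts, Note Extraction and Topic Enrichment for
    Contraceptive Prescription Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds contraceptive-switching cohorts from structured
    medication orders (modality mapping via an editable pattern table,
    attrition filtering, switch detection between consecutive encounters),
    extracts started/stopped/reason triples from clinical note text with a
    pluggable rule-based extractor, scores extractions against gold and
    silver-standard labels (micro F1, accuracy, hallucination rate, Cohen's
    kappa, learning curves), clusters free-text switching rationales into
    topics (term embedding, spectral reduction, density clustering,
    class-based key terms), and computes a log-scaled topic-by-subgroup
    enrichment score stratified by race/ethnicity or age. Ships a seeded
    synthetic electronic-health-record generator with planted switch
    dynamics, reason topics, subgroup enrichments and documentation noise so
    the full pipeline is testable end to end without access to clinical data.
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
    yaml,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
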