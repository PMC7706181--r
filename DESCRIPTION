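Package: crowdcurate
Title: Crowdsourced Validation of Biomedical Relation Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating distantly supervised biomedical relation
    corpora with paid crowdsourcing. Builds classification task batches from a
    phenotype-gene relation corpus, ingests crowd results in the Mechanical
    Turk batch-results dialect, adjudicates multi-worker votes with a
    majority-consensus rule (exclusion at half the votes, plurality for true,
    default false), computes inter-rater agreement (Fleiss' kappa and nominal
    Krippendorff's alpha) with Landis-Koch qualitative bands, models campaign
    costs and worker statistics, and merges adjudicated partitions into a new
    corpus release with class-weight suggestions for downstream relation
    extraction systems. A synthetic campaign generator with per-worker
    confusion-matrix reliability makes the full pipeline testable without any
    crowd data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
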