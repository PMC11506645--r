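Package: dsphenotype
Title: Rule-Based Identification of Down Syndrome in Administrative Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a computable phenotype for Down syndrome in linked
    birth-certificate and healthcare-claims data: a three-criteria classifier
    over karyotype-aware birth-certificate indications and ICD-9 (758.0) /
    ICD-10 (Q90 family) coded encounters during the first six years of life.
    Provides schema-validated readers for the four delimited input tables,
    per-child follow-up window construction with censoring, the classifier
    itself, validation against chart-review gold-standard labels (positive
    predictive value and true-negative proportion with Wilson score
    intervals, plus a criterion-combination breakdown), and a synthetic
    cohort generator for end-to-end testing and recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
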