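Package: birthlink
Title: Record Linkage of Birth Registers to a Social-Registry Cohort
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Links live-birth register records to a social-registry cohort
    baseline using maternal identifying attributes. Provides name
    standardization and invalid-name screening, inverted-index blocking with
    a tiered exact / semi-fuzzy / fuzzy query cascade, weighted similarity
    scoring with Jaro-Winkler, Hamming and Damerau-Levenshtein comparators,
    one-to-one greedy link assignment, ROC-based threshold selection from a
    stratified labeled sample, and linkage-quality and bias reporting.
    Includes a synthetic register generator with ground-truth match labels
    so every stage can be validated without confidential source data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
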