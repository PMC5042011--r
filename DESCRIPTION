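Package: radsens
Title: Radiosensitivity Prediction from Gene and lncRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for building and validating a
    transcriptomic radiosensitivity classifier. Screens an irradiation
    time-course for differentially expressed probes with one-way ANOVA,
    Tukey's HSD and a fold-change filter; extracts co-expressed
    gene-lncRNA pairs from a weighted co-expression network (soft
    thresholding, topological overlap, tree-cut modules); selects a
    fixed-size predictor panel with a genetic algorithm whose fitness is
    cross-validated linear-SVM accuracy on an SF2-dichotomized cell
    panel; quantifies the selected panel against a permutation null of
    random predictor subsets; and validates the frozen classifier in
    patient cohorts with Kaplan-Meier, log-rank and Cox regression
    stratified by radiotherapy status. Ships seeded synthetic-data
    generators that emulate the statistical structure of each study
    stage so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
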