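Package: copdengage
Title: Engagement Phenotyping and Exacerbation Risk Modelling for COPD
    Self-Management Diaries
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to phenotype how users of a COPD self-management app
    engage with daily symptom diaries around exacerbations, to simulate
    engagement-group-conditioned symptom-report series from empirical
    day-offset distributions, and to quantify how engagement and
    transitional behaviour change the performance of a short-horizon
    (3-day) exacerbation risk model. Includes diary ingestion and
    rescue-pack event identification, engagement/quality classification,
    a two-layer synthetic-data generator, rolling-window feature
    construction, a gradient-boosted-tree risk model with grouped
    cross-validation and budgeted hyperparameter search, stratified
    AUROC/average-precision evaluation with bootstrap confidence
    intervals, and descriptive event-aligned analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
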