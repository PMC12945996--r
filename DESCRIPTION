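Package: faerspv
Title: Disproportionality Signal Detection and Risk Modelling for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance toolkit for spontaneous adverse-event report
    databases in the FAERS quarterly-extract dialect. Reads and cleans
    "$"-delimited DEMO/DRUG/REAC/THER tables (case deduplication by latest
    FDA date, drug-role filtering, synonym-based drug matching, PT-to-SMQ
    event mapping, age and weight unit normalisation), computes
    disproportionality statistics per drug-event pair (reporting odds ratio,
    proportional reporting ratio with Pearson chi-squared, and the Bayesian
    confidence propagation neural network information component with its
    uncertainty bound), performs time-to-onset analysis with validity
    exclusions and quartile summaries, and fits univariable and multivariable
    logistic models of event reporting on demographic and treatment
    covariates. A synthetic report generator with planted signals, duplicate
    case versions, partial dates, and configurable missingness makes the full
    pipeline testable without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
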