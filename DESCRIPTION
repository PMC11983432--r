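Package: pvsignal
Title: Disproportionality Signal Detection and Profiling for Spontaneous
    Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of individual case safety
    reports: ingestion and screening of spontaneous report databases
    (primary-suspect filtering, deduplication, validity checks), stratified
    descriptive adverse-drug-reaction profiles at MedDRA system-organ-class
    and preferred-term level, four disproportionality algorithms (reporting
    odds ratio, proportional reporting ratio, the BCPNN information
    component, and an observed/expected EBGM-style ratio) with their 95%
    interval signal criteria, cross-drug shared/unique signal comparison,
    and a seeded synthetic report generator with planted drug-event
    associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
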