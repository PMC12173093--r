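Package: phenovis
Title: Digital-Phenotyping Analytics and Comparative Visualization for
    Relapse Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics pipeline for smartphone digital-phenotyping studies in
    serious mental illness. Imputes sparse ordinal survey responses (last
    observation carried forward, or chained-equations imputation), derives
    per-section multiple correspondence analysis (MCA) trends with eigengap
    consistency diagnostics, condenses ensembles of date clusterings into
    coassociation matrices, summarizes GPS traces into daily home-time and
    significant-location dwell distributions, and compares control versus
    pre-relapse windows. Ships a synthetic cohort generator emulating the
    relapse signatures the pipeline targets (response-variance inflation and
    elevated home time in the month before relapse), plus static two-panel
    comparative HTML reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
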