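Package: wearagree
Title: Agreement and Telemonitoring Analytics for Smartwatch Vital Signs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for validating consumer wearable vital-sign measurements
    against gold-standard devices in longitudinal telemonitoring cohorts.
    Implements tolerance-region consolidation of triplicate readings,
    Bland-Altman limits of agreement for repeated measures via one-way
    ANOVA variance components, error-band fractions and error-trend
    regression, independent-samples group comparisons, MANOVA profile
    analysis of 24-hour heart-rate curves (level, flatness and parallelism
    hypotheses), hypnogram harmonization and sleep-architecture metrics
    (TIB, TST, SE, latency, WASO), vital-sign alert rules, and
    synchronization-latency accounting. A seeded synthetic-data generator
    emulates the paired-device measurement structure of an 80-volunteer
    smartwatch telemonitoring cohort so the full pipeline is testable
    without access to the original records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
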