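Package: faersignal
Title: Disproportionality Signal Detection and Prioritisation for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance screening of
    FAERS-style quarterly spontaneous-report extracts: reading and
    deduplicating the $-delimited DEMO/DRUG/REAC/OUTC/RPSR/THER/INDI tables,
    building a primary-suspect drug cohort, four-method disproportionality
    analysis (reporting odds ratio, proportional reporting ratio, BCPNN
    information component, empirical Bayes geometric mean with an optional
    gamma-Poisson shrinker) at preferred-term and system-organ-class level
    with age and sex subgroups, clinical-priority scoring of positive
    signals against designated/important medical event lists, and
    time-to-onset analysis with Weibull failure-type classification and
    Kaplan-Meier cumulative-incidence curves. Includes a synthetic
    report generator with planted drug-event associations so every stage is
    testable without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    survival,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
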