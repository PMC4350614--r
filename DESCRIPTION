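Package: methage
Title: Epigenetic Clock Age Acceleration, Mortality Association, and Heritability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring DNA methylation age (epigenetic clocks) from
    Illumina-style beta-value matrices, constructing the accelerated-aging
    statistic delta-age (methylation age minus chronological age) with
    technical and cell-count adjustments, testing its association with
    all-cause mortality through Cox proportional-hazards models pooled by
    inverse-variance fixed-effect meta-analysis, and estimating the
    pedigree-based heritability of delta-age via relationship-class
    intraclass correlations and a restricted-maximum-likelihood additive
    variance-component model. A synthetic-data generator produces cohorts,
    beta matrices with a known true clock, proportional-hazards survival
    times, and twin-family pedigrees so that every stage of the pipeline is
    testable without access-controlled cohort data.
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
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
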