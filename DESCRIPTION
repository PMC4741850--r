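Package: prostvar
Title: Case-Only Germline Variant Prioritization for Familial Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable workflow for case-only genetic evaluation of familial
    prostate cancer: assembly of a candidate gene panel from heterogeneous
    source lists with alias normalization and locus-type exclusions,
    quality/consequence/rarity filtering of annotated germline variant tables,
    consensus in-silico damage classification over five pathogenicity
    predictors, annotation against ExAC-style population allele-frequency
    tables, per-patient and cohort-level reporting with a DNA damage response
    (DDR) focus, and rank-based statistics (group comparison, Youden-optimal
    cutoffs, ROC/AUC) for gamma-H2AX foci functional assays. Ships an encoded
    12-patient study as plain-text fixtures and a seeded synthetic-data
    generator so every stage runs without downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
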