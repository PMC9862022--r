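Package: bcprog
Title: Receptor Subtyping, Differential Expression and Survival Screening
    for Breast-Cancer Prognosis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for transcriptome-based prognosis
    analysis of breast-cancer cohorts split into normal tissue, good-prognosis
    (alive beyond five years) and poor-prognosis (dead within five years)
    groups. Determines ER/PR/HER2 positivity thresholds by two-component
    Gaussian mixture deconvolution of log10 expression and assigns surrogate
    intrinsic subtypes; runs per-gene Welch t differential expression with
    Benjamini-Hochberg adjustment and volcano classification; selects
    prognosis-group-specific gene sets; screens genes for survival effect by
    tertile stratification with Kaplan-Meier estimation and log-rank tests;
    and computes clinical contingency statistics (Fisher exact, logistic
    regression, ANOVA with Tukey post-test). Includes a synthetic cohort
    generator with planted ground truth so the whole pipeline is testable
    without patient data.
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
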