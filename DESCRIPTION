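Package: ubistrat
Title: Copy-Number Ubiquitination Signatures for Tumor Stratification and
    Clinical Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stratifies breast-cancer cohorts by a two-gene SKP2-ubiquitination
    signature that compares the discrete copy-number level of the APC/C
    co-activator FZR1 against that of a deubiquitinase (USP10 or USP13), and
    runs the downstream validation and clinical-association pipeline: p27
    proxy comparisons (one-way ANOVA, Welch t), empirical-Bayes moderated-t
    differential expression with log-fold-change concordance between
    signature- and SKP2-copy-number contrasts, Kaplan-Meier/log-rank survival
    analysis, chi-square association with tumor stage and grade, negative
    binomial regression of positive-lymph-node counts, and a bidirectional
    Kolmogorov-Smirnov connectivity screen of ranked perturbation profiles
    for drug repurposing. Includes a synthetic-cohort generator that emulates
    the statistical structure of public breast-cancer datasets so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    jsonlite,
    limma,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
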