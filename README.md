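# ubistrat

Patient stratification by a two-gene **SKP2-ubiquitination signature** and the
downstream validation and clinical-association pipeline, for breast-cancer
cohorts with discrete copy-number calls.

SKP2 is the substrate-recognition subunit of the SCF E3 ubiquitin ligase and an
oncoprotein: it marks the cell-cycle inhibitors p27/p21 for degradation. SKP2
itself is ubiquitinated by APC/C^FZR1 and deubiquitinated by USP10/USP13. The
signature compares the cBioPortal-style copy-number level
(−2 deep loss, −1 shallow loss, 0 diploid, 1 gain, 2 amplification) of the
ligase co-activator against the deubiquitinase:

| group | rule | expected SKP2 | expected p27 |
|---|---|---|---|
| high ubiquitination | CN(FZR1) > CN(USP10) | low | high |
| intermediate | CN(FZR1) = CN(USP10) | intermediate | intermediate |
| low ubiquitination | CN(FZR1) < CN(USP10) | high | low |

An expression-median variant handles datasets without copy-number calls:
FZR1 ≤ median and USP10 > median is low ubiquitination, the mirror image is
high, everything else intermediate.

Around the classifier the package implements the full analysis the signature
is validated with:

- **Proxy validation** — one-way ANOVA and Welch *t* on p27 (RPPA-style) across
  groups; from-scratch empirical-Bayes **moderated-t** differential expression
  (method-of-moments prior on log-variances, posterior variance
  (d₀s₀² + d·s²)/(d₀ + d), BH adjustment); Spearman concordance between the
  per-gene log-fold-change vectors of the signature contrast and of the SKP2
  copy-number contrast.
- **Clinical association** — Kaplan–Meier curves and the log-rank test on
  overall survival; chi-square tests of independence against tumor stage and
  grade; hand-rolled **NB2 GLM** (IRLS for the coefficients alternating with
  Newton's method on the digamma score for θ, Wald z tests) for
  positive-lymph-node counts with the high-ubiquitination group as baseline.
- **Drug repurposing** — bidirectional Kolmogorov–Smirnov **connectivity
  scores** of ranked perturbation profiles against an up/down query signature,
  a permutation screen with BH FDR and a "recommended" label for significant
  reversers, and ln-IC50 potency comparisons (ANOVA + starred pairwise *t*
  tests vs a reference drug).
- **Synthetic cohorts** — a generator that emulates the statistical structure
  of public breast-cancer datasets (discrete CN marginals, IHC subtype
  mixture, group-shifted p27, exponential survival with tuned uniform
  censoring, proportional-odds stage/grade, NB node counts with planted
  coefficients, expression driven by a latent SKP2-activity factor, reference
  profiles with planted reversing drugs) so the whole pipeline is testable
  without downloads.

## Worked example

```r
library(ubistrat)

cfg    <- sim_config(n_patients = 2000, seed = 42)
cohort <- simulate_cohort(cfg) |> stratify_cohort()

group_counts(cohort) |> tidyr::pivot_wider(names_from = subtype, values_from = n)
#>   ubiq_group   luminal  her2  tnbc other
#> 1 high             368    31    80    36
#> 2 intermediate     671    63   142    66
#> 3 low              395    23    79    46
#> 4 unclassified       0     0     0     0

survival_by_group(dplyr::filter(cohort, subtype == "luminal"))
#> Log-rank test: chi2 = 26.63, df = 1, p = 2.458e-07
#>   group observed expected     n
#> 1 high       153     203.   368
#> 2 low        224     174.   395

lum <- dplyr::filter(cohort, subtype == "luminal", ubiq_group != "unclassified")
fit_negbin_glm(lum$positive_nodes, droplevels(lum$ubiq_group))
#> Negative binomial GLM (log link), theta = 0.2397
#>   term         estimate std.error statistic   p.value stars
#> 1 (Intercept)     0.489     0.114      4.29 0.0000181 ***
#> 2 intermediate    0.404     0.141      2.87 0.00416   **
#> 3 low             0.481     0.157      3.07 0.00212   **

lfc_concordance(simulate_expression(cfg, cohort), cohort)
#> LFC concordance (signature vs SKP2 CN): rho = 0.4474, p = 5.193e-99, 2000 genes
```

Read the output as a clinician would: low-ubiquitination patients (deubiquitinase
dosage exceeding ligase dosage, hence stabilized SKP2) die faster than
high-ubiquitination patients (224 deaths observed vs 174 expected under the
null), and carry more positive lymph nodes (the `low` coefficient 0.48 is the
log-ratio of expected node counts vs the high group; here the generator planted
0.43/0.29/0.58). The concordance ρ ≈ 0.45 says the signature's transcriptional
footprint tracks the footprint of SKP2 copy-number dosage.

Every fitted object has broom-style `tidy()`/`glance()` methods and a ggplot2
`autoplot()` (plus `plot_p27_groups()`, `plot_survival_groups()`), and
`run_pipeline(run_config(...))` orchestrates all stages end to end with a
reconciling manifest and TSV outputs.

## Vignette

`vignettes/ubiquitination-signature.Rmd` documents the model, the generator's
assumptions and defaults, numerical choices (dispersion estimation, shrinkage
hyperparameters, KS normalization, tie conventions) and known limitations.
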