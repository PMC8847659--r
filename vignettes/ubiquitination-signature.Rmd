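---
title: "The SKP2-ubiquitination signature: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SKP2-ubiquitination signature: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubistrat)
```

## The signature and why it works

SKP2 targets the CDK inhibitors p27 and p21 for proteasomal degradation, so
high SKP2 activity removes a brake on the cell cycle and is oncogenic. SKP2
protein levels are themselves set by a ubiquitination balance: APC/C with its
co-activator FZR1 ubiquitinates SKP2, while the deubiquitinases USP10 and
USP13 remove that mark. `ubistrat` operationalizes this balance as a two-gene
copy-number comparison: a patient whose FZR1 copy-number level exceeds the
USP10 level is presumed to ubiquitinate (and hence degrade) SKP2 efficiently
— the *high-ubiquitination* group, with low SKP2 and high p27 — while the
opposite inequality defines the *low-ubiquitination* group, and equality the
*intermediate* group. Copy number rather than expression is used because it
is the more stable, more prognostic aberration class; discrete cBioPortal
levels (−2…2) make the comparison trivial for clinical use.

Two classifiers implement this: `classify_cn()` on copy-number levels, and
`classify_expression()` for expression-only datasets, which splits on
dataset-wide medians of FZR1 and USP10 (with "at or below the median" taken
literally, so a sample exactly at both medians is intermediate). Missing
input yields `unclassified`; such patients are counted and excluded from
analyses, never silently dropped. IHC subtypes follow the standard receptor
rules (`assign_subtype()`): ER+ is luminal, ER−/PR−/HER2+ is HER2,
triple-negative is TNBC, everything else (including unknowns) "other".

## What the pipeline computes

* **p27 proxy check.** If the signature tracks SKP2 activity, p27 (an
  RPPA-style continuous protein value, arbitrary units) should decrease from
  the high to the low group. `one_way_anova()` tests the three-group pattern;
  `welch_t_test()` compares high vs low. Welch is the default for the pairwise
  comparison because it is robust to unequal group variances; `pooled = TRUE`
  restores the classical Student form for users who want it.
* **Transcriptional footprint.** `fit_gene_lfc()` computes per-gene log2 fold
  changes with pooled variances; `moderated_t()` shrinks the per-gene
  variances with the standard empirical-Bayes scaled-F model and BH-adjusts
  the p-values. `lfc_concordance()` then correlates (Spearman) the all-gene
  LFC vector of the signature contrast with that of a SKP2 copy-number
  contrast. Both contrasts are oriented toward increasing SKP2 activity —
  low-minus-high ubiquitination, and SKP2-gained (level ≥ 1) minus
  normal-or-lost (level ≤ 0) — so a signature that genuinely proxies SKP2
  dosage produces a *positive* rank correlation. The ≥1 / ≤0 dichotomy is a
  design choice: the discrete levels offer no other natural "high vs
  normal-or-low" split.
* **Clinical outcome.** `survival_by_group()` compares overall survival with
  the log-rank test, by default high vs low with intermediate excluded — the
  signature's clinical claim concerns its two extreme groups — while
  `three_group = TRUE` keeps intermediate as its own stratum (the natural
  choice for the expression-median variant, where intermediate is the
  majority). Stage and grade associations use `chi_square_independence()`
  (no continuity correction; a flag marks expected cells below 5). Survival
  time units are whatever the cohort provides (months from the simulator);
  the tests are unit-invariant.
* **Node counts.** Positive-lymph-node counts are overdispersed
  (variance ≫ mean), so `fit_negbin_glm()` fits an NB2 GLM with log link,
  `count ~ group`, baseline = high ubiquitination. Positive coefficients mean
  more positive nodes than the high group. Note the intercept's Wald test has
  null "expected count = 1", which is a scientifically arbitrary reference;
  it is reported because the conventional regression table includes it, not
  because it answers a biological question.
* **Repurposing.** `build_query_signature()` takes the significantly up- and
  down-regulated genes (each set capped at the `max_set` strongest by
  |moderated t|), `connectivity_screen()` scores every ranked reference
  perturbation profile with the bidirectional KS statistic and a permutation
  null, and drugs whose profiles significantly *reverse* the signature
  (score < 0, BH FDR < 0.05) are labelled recommended. `compare_ic50()`
  compares potencies on the natural-log IC50 scale (the convention of the
  public drug-sensitivity releases) with ANOVA plus starred pairwise Welch
  tests against a reference drug.

## The synthetic-cohort generator

`sim_config()`/`simulate_cohort()` emulate the joint structure the analyses
assume; defaults are chosen once to be realistic for a METABRIC/TCGA-scale
breast-cancer cohort and are not tuned to any test:

* `n_patients = 2000`, subtype mix 72% luminal / 6% HER2 / 15% TNBC /
  7% other — luminal-dominant, as in real registries.
* Copy-number marginals default to (0.03, 0.14, 0.66, 0.14, 0.03) per gene,
  drawn independently per gene (no joint CN distribution is assumed anywhere;
  a correlated-marginals extension would slot in here). Under independence
  this symmetric marginal yields roughly 26/48/26 percent
  high/intermediate/low. The true marginal frequencies for these genes are
  not published; these defaults are documented as arbitrary.
* Group effects apply to **luminal patients only** by default
  (`group_scope = "luminal"`), mirroring the subtype specificity the pipeline
  is designed to detect; `"all"` applies them cohort-wide (used in tests that
  need maximal signal per patient).
* p27 is Gaussian with a mean shift of `p27_effect` (default 0.3 units) per
  group step and residual SD `p27_sd = 1`.
* Survival is exponential at `baseline_hazard = 0.01`/month (median ≈ 69
  months) with hazard multiplied by `hazard_ratio_low_vs_high = 1.5` for the
  low group. Censoring times are uniform on [0, T]; T is solved by bisection
  on the deterministic identity E[censored] = mean(min(tᵢ/T, 1)) so the
  realized censor fraction hits `censor_fraction_target = 0.55` (roughly the
  alive fraction of long-follow-up registry data). Uniform censoring was
  chosen as the simplest mechanism independent of group.
* Stage (I–IV) and grade (1–3) come from proportional-odds multinomials whose
  cumulative logits shift by `stage_grade_shift = 0.5` per group step toward
  higher categories in the low group.
* Node counts are NB with log-mean `0.43 + 0.29·[intermediate] + 0.58·[low]`
  and dispersion θ = `derive_theta(1.80, 14.52)` ≈ 0.2547 — the planted
  regression truths, with θ obtained by inverting the NB2 variance identity
  var = μ + μ²/θ on the luminal count moments.
* The hidden SKP2-activity variable is
  `latent_skp2 = −(group step) + 0.8·CN(SKP2) + N(0,1)`: ubiquitination
  degrades SKP2 (the −step term) and copy-number gain raises it (the dosage
  term). The dosage term is essential — without it the SKP2-copy-number
  expression contrast would be statistically independent of the planted
  factor and the concordance analysis would have nothing to detect.
  `simulate_expression()` gives a configurable fraction of genes
  (default 20%) a loading ~ N(0, `expr_effect_sd`) on this latent variable;
  the four signature genes additionally gain 0.5 log2 units per own
  copy-number level.
* `simulate_reference_profiles()` builds ranked perturbation lists; planted
  reversers place the query's down-set at the top and up-set at the bottom,
  all other profiles are uniform permutations.

Each `simulate_*` call seeds its own stream (expression at `seed + 1`) so
identical configurations are bit-reproducible and partial re-runs stay
stable. What the generator does **not** emulate: probe-level microarray
artefacts and normalization, copy-number calling from segmented data, joint
CN correlation between genes, non-proportional hazards, informative
censoring, and any real drug's transcriptional profile. Passing tests
therefore demonstrate that the *statistics* are implemented correctly and
recover planted truths — not that the biological claims hold on real data.

## Numerical choices

* **Moderated t.** The prior (d₀, s₀²) is estimated by method of moments on
  log s² under the scaled-F model: the excess of var(log s²) over the
  chi-square term trigamma(d/2) is inverted through the trigamma function
  (Newton, with the standard series start). Non-positive excess spread gives
  d₀ = ∞ — full shrinkage to the common variance — as a valid limit, not an
  error; d₀ = 0 reproduces the ordinary t exactly. p-values use d + d₀
  degrees of freedom.
* **NB2 fitting.** Coefficients and dispersion are alternated: IRLS with
  expected-information weights μ/(1 + μ/θ) for β given θ, Newton with
  step-halving on the profile digamma score for θ given β, until the
  log-likelihood changes by < 1e−8 (≤ 100 outer rounds; the trace is exposed
  and is non-decreasing). θ is initialized by method of moments on the
  Pearson residuals of a Poisson fit. Equidispersed input drives θ to the
  Poisson limit; it is capped at 1e6 with a warning rather than failing.
  Wald p-values use the normal reference, matching conventional NB regression
  summaries.
* **Connectivity score.** For each gene set the one-sided running-sum KS
  statistic is a = max(j/t − V(j)/n) vs b = max(V(j)/n − (j−1)/t), signed by
  whichever is larger; the bidirectional raw score is ks_up − ks_down only
  when the two disagree in sign, else 0. Raw scores are normalized by the
  extreme attainable raw score for the given set sizes (sets flush at the
  list ends), separately for the positive and negative directions, so planted
  concordant/reversing profiles score exactly ±1 even with unequal set sizes.
  Swapping the up and down sets negates the score exactly; reversing the
  reference list negates it up to O(1/n) tie effects inherent to the
  asymmetric (j−1)/t term. Permutation p-values are the plain Monte-Carlo
  fraction of same-size random set pairs scoring at least as extremely
  (two-sided on |score|, no +1 correction, so a profile beating every
  permutation earns p = 0 as in classic connectivity screens); BH adjusts
  across profiles.
* **Spearman p.** The t approximation t = ρ√((n−2)/(1−ρ²)) on n−2 df,
  two-tailed; |ρ| = 1 reports p = 0. Constant input is an error (rank
  correlation undefined under zero rank variance).
* **Degenerate inputs.** ANOVA with zero between- and within-variance returns
  F = 0, p = 1 (and F = ∞, p = 0 when only the within-variance vanishes);
  two constant samples with equal means give t = 0, p = 1, with unequal means
  an explicit degenerate-variance error; a log-rank call with no events, a
  chi-square table with a zero marginal, and an all-zero count vector are
  errors.
* **I/O.** All tables are UTF-8 TSV with "NA" sentinels. Numeric columns are
  parsed with the correctly-rounded base converter so that
  write → read → write is bit-identical.

## Scale of the validation runs

The test-suite and acceptance-script simulations use sizes chosen to make the
Monte-Carlo error small relative to the tolerances they check: 1000
replicate count vectors of n = 1500 (groups 25/50/25%) for coefficient
recovery and Wald coverage, 2000 null survival datasets of n = 200 (30%
censoring) for log-rank calibration, 5000 genes for null uniformity and
concordance levels, 500 replicates for FDR control, and a 51-profile screen
with 1000 permutations for reverser recovery. Marginal-fidelity checks use
n = 50,000 draws.

## Interface note

The package is used from R: the exported functions, `run_config()` (with a
flat YAML mirror via `read_run_config()`) and `run_pipeline()` are the
interface, and `scripts/acceptance.R` is the scripted entry point for
regenerating the headline numbers. No separate shell executable is shipped.

## Known limitations

* The signature treats the discrete copy-number comparison as exact; a
  one-level difference and a four-level difference are the same group.
* The two-group survival default discards intermediate patients (roughly half
  a typical cohort); the three-group mode keeps them but answers a different
  question.
* The connectivity screen scores profiles independently; it does not model a
  drug's replicate structure across cell lines, and its statistic is the
  classical bidirectional KS score, not any specific published tool's
  internal variant.
* The permutation p without the +1 correction is mildly anticonservative;
  the empirical-FDR acceptance check bounds the practical effect.
* The simulator's exponential survival and uniform censoring are convenient,
  not realistic; hazard-shape misspecification on real data is untested here.
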