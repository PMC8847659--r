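# Synthetic cohort, expression and reference-profile generators.
#
# The generator emulates the statistical structure the downstream analyses
# assume in public breast-cancer cohorts: discrete per-gene copy-number
# marginals, an IHC subtype mixture, group-dependent p27 shifts, exponential
# survival with group-dependent hazard and uniform censoring tuned to a target
# censor fraction, proportional-odds stage/grade distributions shifted by
# signature group, and negative-binomially distributed positive-lymph-node
# counts with planted regression coefficients.

#' Negative-binomial dispersion from moments
#'
#' Inverts the NB2 variance identity `var = mu + mu^2 / theta` to recover the
#' dispersion from a sample mean and variance. Smaller theta means stronger
#' overdispersion.
#'
#' @param mean Positive sample mean of the counts.
#' @param variance Sample variance; must exceed the mean (overdispersion).
#' @return The dispersion theta = mean^2 / (variance - mean).
#' @export
#' @examples
#' derive_theta(1.80, 14.52)  # luminal positive-node counts
derive_theta <- function(mean, variance) {
  check_scalar_pos(mean, "mean")
  check_scalar_pos(variance, "variance")
  if (variance <= mean) {
    abort("not overdispersed; NB reduces to/below Poisson (variance <= mean)")
  }
  mean^2 / (variance - mean)
}

#' Simulation configuration for synthetic cohorts
#'
#' Collects all parameters of the synthetic-cohort generator with validated
#' defaults. Group effects (p27 shift, survival hazard ratio, stage/grade
#' shift, node-count coefficients) apply to luminal patients only by default
#' (`group_scope = "luminal"`), mirroring the subtype-specificity the pipeline
#' is designed to detect; `group_scope = "all"` applies them cohort-wide.
#'
#' @param n_patients Number of patients (>= 10).
#' @param subtype_proportions Named probabilities for luminal/her2/tnbc; the
#'   remainder is "other".
#' @param cn_marginals Named list of probability vectors over copy-number
#'   levels \{-2,-1,0,1,2\} for fzr1, usp10, usp13, skp2. The default is a
#'   symmetric marginal (0.03, 0.14, 0.66, 0.14, 0.03) for every gene, which
#'   under independence yields roughly 26/48/26 percent high/intermediate/low.
#' @param p27_effect Mean shift of p27 per group step (high > intermediate >
#'   low), applied within `group_scope`.
#' @param p27_sd Residual standard deviation of p27.
#' @param n_genes Number of genes in the simulated expression matrix.
#' @param frac_responsive Fraction of genes linked to the latent SKP2 activity.
#' @param expr_effect_sd SD of the per-gene loading on latent SKP2 activity.
#' @param baseline_hazard Exponential event hazard per month.
#' @param hazard_ratio_low_vs_high Hazard multiplier for the low-ubiquitination
#'   group (within `group_scope`).
#' @param censor_fraction_target Target fraction of censored patients in
#'   \[0, 1\]; censoring times are uniform on \[0, T\] with T solved by
#'   bisection.
#' @param stage_grade_shift Proportional-odds log-odds shift toward higher
#'   stage/grade per group step (within `group_scope`).
#' @param nb_coefficients Log-scale NB regression truth
#'   (intercept = high group, intermediate, low) for positive-node counts.
#' @param nb_theta NB2 dispersion of node counts.
#' @param group_scope `"luminal"` (default) or `"all"`.
#' @param seed Integer seed; identical configs give bit-identical tables.
#' @return A validated list of class `ubistrat_sim_config`.
#' @export
sim_config <- function(n_patients = 2000L,
                       subtype_proportions = c(luminal = 0.72, her2 = 0.06, tnbc = 0.15),
                       cn_marginals = NULL,
                       p27_effect = 0.3,
                       p27_sd = 1,
                       n_genes = 2000L,
                       frac_responsive = 0.2,
                       expr_effect_sd = 0.5,
                       baseline_hazard = 0.01,
                       hazard_ratio_low_vs_high = 1.5,
                       censor_fraction_target = 0.55,
                       stage_grade_shift = 0.5,
                       nb_coefficients = c(intercept = 0.43, intermediate = 0.29, low = 0.58),
                       nb_theta = derive_theta(1.80, 14.52),
                       group_scope = c("luminal", "all"),
                       seed = 1L) {
  group_scope <- match.arg(group_scope)
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    abort("`n_patients` must be a positive integer")
  }
  if (length(subtype_proportions) != 3L ||
      any(subtype_proportions < 0) || sum(subtype_proportions) > 1 + 1e-9) {
    abort("`subtype_proportions` must be three non-negative probabilities summing to <= 1")
  }
  p4 <- c(subtype_proportions, other = max(0, 1 - sum(subtype_proportions)))
  names(p4) <- subtype_levels
  check_prob_vector(p4, "subtype_proportions (with remainder)")
  if (is.null(cn_marginals)) {
    m <- c(0.03, 0.14, 0.66, 0.14, 0.03)
    cn_marginals <- list(fzr1 = m, usp10 = m, usp13 = m, skp2 = m)
  }
  need <- c("fzr1", "usp10", "usp13", "skp2")
  if (!all(need %in% names(cn_marginals))) {
    abort("`cn_marginals` must name fzr1, usp10, usp13 and skp2")
  }
  for (g in need) {
    if (length(cn_marginals[[g]]) != 5L) {
      abort(sprintf("cn_marginals$%s must have 5 probabilities (levels -2..2)", g))
    }
    check_prob_vector(cn_marginals[[g]], paste0("cn_marginals$", g))
  }
  check_scalar_pos(p27_sd, "p27_sd")
  check_scalar_pos(baseline_hazard, "baseline_hazard")
  check_scalar_pos(hazard_ratio_low_vs_high, "hazard_ratio_low_vs_high")
  check_scalar_pos(nb_theta, "nb_theta")
  if (censor_fraction_target < 0 || censor_fraction_target > 1) {
    abort("`censor_fraction_target` must lie in [0, 1]")
  }
  if (frac_responsive < 0 || frac_responsive > 1) {
    abort("`frac_responsive` must lie in [0, 1]")
  }
  check_scalar_pos(n_genes, "n_genes")
  if (length(nb_coefficients) != 3L) {
    abort("`nb_coefficients` must be (intercept, intermediate, low)")
  }
  names(nb_coefficients) <- c("intercept", "intermediate", "low")
  structure(list(
    n_patients = as.integer(n_patients),
    subtype_proportions = p4,
    cn_marginals = cn_marginals,
    p27_effect = p27_effect, p27_sd = p27_sd,
    n_genes = as.integer(n_genes),
    frac_responsive = frac_responsive, expr_effect_sd = expr_effect_sd,
    baseline_hazard = baseline_hazard,
    hazard_ratio_low_vs_high = hazard_ratio_low_vs_high,
    censor_fraction_target = censor_fraction_target,
    stage_grade_shift = stage_grade_shift,
    nb_coefficients = nb_coefficients, nb_theta = nb_theta,
    group_scope = group_scope,
    seed = as.integer(seed)
  ), class = "ubistrat_sim_config")
}

# Group "step": +1 high, 0 intermediate, -1 low; NA for unclassified.
group_step <- function(group) {
  c(high = 1, intermediate = 0, low = -1, unclassified = NA_real_)[as.character(group)]
}

# Uniform-censoring horizon: solve mean(pmin(t/T, 1)) = target for T by
# bisection; the left side is the expected censor fraction when censoring
# times are U(0, T), decreasing in T.
solve_censor_horizon <- function(t, target) {
  if (target <= 0) return(Inf)
  f <- function(T) mean(pmin(t / T, 1)) - target
  lo <- max(min(t), 1e-8)
  hi <- max(t) * 2
  while (f(hi) > 0) hi <- hi * 2
  while (f(lo) < 0) lo <- lo / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Proportional-odds draw: base category probabilities `probs`, linear
# predictor eta shifts mass toward higher categories when positive.
draw_prop_odds <- function(probs, eta, labels) {
  k <- length(probs)
  cuts <- qlogis(cumsum(probs)[-k])
  cum <- plogis(outer(eta, cuts, function(e, c) c - e))  # n x (k-1), P(Y <= j)
  u <- runif(length(eta))
  idx <- rowSums(u > cum) + 1L
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Simulate a synthetic breast-cancer cohort
#'
#' Draws one patient table under the configuration returned by [sim_config()].
#' Copy-number levels are drawn independently per gene from the configured
#' marginals; the ubiquitination group implied by FZR1 vs USP10 then drives
#' the planted effects. The hidden column `latent_skp2` equals minus the group
#' step (high ubiquitination implies low SKP2 activity) plus 0.8 times the
#' SKP2 copy-number level (dosage) plus standard normal noise, and is what the
#' simulated expression responds to.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional override of `config$seed`.
#' @return A tibble with one row per patient: `patient_id`, receptor statuses,
#'   `subtype`, copy-number levels, `p27`, `os_time` (months), `os_event`,
#'   `stage`, `grade`, `positive_nodes`, `latent_skp2`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 200, seed = 7))
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ubistrat_sim_config"))
  if (config$n_patients < 10) abort("cohort too small")
  withr::local_seed(seed %||% config$seed)
  n <- config$n_patients

  subtype <- factor(
    sample(subtype_levels, n, replace = TRUE, prob = config$subtype_proportions),
    levels = subtype_levels
  )
  # Receptor statuses consistent with the IHC subtype definitions.
  er <- ifelse(subtype == "luminal", "positive", "negative")
  pr <- rep("negative", n)
  pr[subtype == "luminal"] <- ifelse(runif(sum(subtype == "luminal")) < 0.7,
                                     "positive", "negative")
  pr[subtype == "other"] <- "positive"
  her2 <- rep("negative", n)
  her2[subtype == "her2"] <- "positive"

  cn <- lapply(config$cn_marginals, function(m) {
    sample(cn_levels, n, replace = TRUE, prob = m)
  })

  group <- classify_cn(cn$fzr1, cn$usp10)
  s <- group_step(group)
  in_scope <- if (config$group_scope == "all") rep(TRUE, n) else subtype == "luminal"
  s_eff <- ifelse(in_scope, s, 0)

  # Latent SKP2 activity: lower under high ubiquitination (more degradation),
  # higher with SKP2 copy-number gain (dosage), plus unit noise. The dosage
  # term is what lets the SKP2 copy-number expression contrast share the
  # planted factor with the signature contrast.
  latent_skp2 <- -s + 0.8 * cn$skp2 + rnorm(n)
  p27 <- config$p27_effect * s_eff + rnorm(n, sd = config$p27_sd)

  rate <- config$baseline_hazard *
    ifelse(group == "low" & in_scope, config$hazard_ratio_low_vs_high, 1)
  t_event <- rexp(n, rate)
  horizon <- solve_censor_horizon(t_event, config$censor_fraction_target)
  if (is.finite(horizon)) {
    c_time <- runif(n, 0, horizon)
    os_time <- pmin(t_event, c_time)
    os_event <- as.integer(t_event <= c_time)
  } else {
    os_time <- t_event
    os_event <- rep(1L, n)
  }

  eta <- config$stage_grade_shift * (-s_eff)
  stage <- draw_prop_odds(c(0.18, 0.55, 0.22, 0.05), eta, c("I", "II", "III", "IV"))
  grade <- draw_prop_odds(c(0.10, 0.40, 0.50), eta, c("1", "2", "3"))

  b <- config$nb_coefficients
  lin <- b[["intercept"]] +
    ifelse(in_scope & group == "intermediate", b[["intermediate"]], 0) +
    ifelse(in_scope & group == "low", b[["low"]], 0)
  positive_nodes <- rnbinom(n, size = config$nb_theta, mu = exp(lin))

  tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    er = er, pr = pr, her2 = her2, subtype = subtype,
    cn_fzr1 = cn$fzr1, cn_usp10 = cn$usp10, cn_usp13 = cn$usp13, cn_skp2 = cn$skp2,
    p27 = p27,
    os_time = os_time, os_event = os_event,
    stage = stage, grade = grade,
    positive_nodes = positive_nodes,
    latent_skp2 = latent_skp2
  )
}

#' Simulate a log2-scale expression matrix tied to a cohort
#'
#' A configured fraction of genes loads on the cohort's hidden SKP2-activity
#' variable (`latent_skp2`), with per-gene loadings drawn from
#' N(0, `expr_effect_sd`); remaining genes are pure noise around a gene
#' baseline. When `n_genes >= 8` the first four rows are the signature genes
#' FZR1, USP10, USP13 and SKP2, whose expression increases monotonically with
#' the patient's own copy-number level (0.5 log2 units per level).
#'
#' @param config A [sim_config()] object.
#' @param cohort A cohort from [simulate_cohort()] (must carry `latent_skp2`).
#'   The expression stream is seeded at `config$seed + 1` so cohort and
#'   expression draws are reproducible independently.
#' @return A numeric genes x samples matrix with gene-id rownames and
#'   patient-id colnames.
#' @export
simulate_expression <- function(config, cohort) {
  stopifnot(inherits(config, "ubistrat_sim_config"))
  if (!"latent_skp2" %in% names(cohort)) {
    abort("cohort lacks the `latent_skp2` column required to simulate expression")
  }
  withr::local_seed(derive_seed(config$seed, 1))
  n <- nrow(cohort)
  G <- config$n_genes
  with_cn_genes <- G >= 8L
  cn_gene_names <- c("FZR1", "USP10", "USP13", "SKP2")
  n_generic <- if (with_cn_genes) G - 4L else G
  gene_ids <- c(if (with_cn_genes) cn_gene_names,
                sprintf("G%05d", seq_len(n_generic)))

  baseline <- rnorm(G, mean = 7, sd = 1)
  vals <- baseline + matrix(rnorm(G * n), G, n)

  generic_rows <- if (with_cn_genes) seq.int(5L, G) else seq_len(G)
  n_resp <- round(config$frac_responsive * length(generic_rows))
  if (n_resp > 0) {
    resp <- sample(generic_rows, n_resp)
    beta <- rnorm(n_resp, sd = config$expr_effect_sd)
    vals[resp, ] <- vals[resp, ] + beta %o% cohort$latent_skp2
  }
  if (with_cn_genes) {
    cn_cols <- c("cn_fzr1", "cn_usp10", "cn_usp13", "cn_skp2")
    for (i in 1:4) {
      lev <- cohort[[cn_cols[i]]]
      lev[is.na(lev)] <- 0
      vals[i, ] <- vals[i, ] + 0.5 * lev
    }
  }
  dimnames(vals) <- list(gene_ids, cohort$patient_id)
  vals
}

#' Simulate a reference perturbation-profile set
#'
#' Builds per-(drug, cell line) ranked gene lists for connectivity screening.
#' `n_reversers` profiles are planted reversers: they place the query down-set
#' at the top of the ranking (most up-regulated) and the query up-set at the
#' bottom, i.e. they oppose the query signature; all remaining profiles are
#' uniform random permutations of the gene universe.
#'
#' @param universe Character vector of gene ids.
#' @param query_up,query_down Disjoint gene sets within `universe`.
#' @param n_drugs Total number of profiles.
#' @param n_reversers Number of planted reversers (<= `n_drugs`).
#' @param seed Integer seed.
#' @param cell_line Cell-line label attached to every synthetic profile.
#' @return A tibble with columns `drug`, `cell_line`, `planted`, and a
#'   list-column `ranked` of gene rankings (most up- to most down-regulated).
#' @export
simulate_reference_profiles <- function(universe, query_up, query_down,
                                        n_drugs, n_reversers, seed = 1L,
                                        cell_line = "SYN1") {
  if (length(intersect(query_up, query_down)) > 0) {
    abort("query up and down sets overlap")
  }
  if (!all(c(query_up, query_down) %in% universe)) {
    abort("query sets must be contained in the gene universe")
  }
  if (n_reversers > n_drugs) abort("`n_reversers` cannot exceed `n_drugs`")
  withr::local_seed(seed)
  rest <- setdiff(universe, c(query_up, query_down))
  make_ranking <- function(reverser) {
    if (reverser) {
      c(sample(query_down), sample(rest), sample(query_up))
    } else {
      sample(universe)
    }
  }
  planted <- seq_len(n_drugs) <= n_reversers
  tibble(
    drug = ifelse(planted,
                  sprintf("reverser_%02d", seq_len(n_drugs)),
                  sprintf("null_%02d", seq_len(n_drugs))),
    cell_line = cell_line,
    planted = planted,
    ranked = lapply(planted, make_ranking)
  )
}
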