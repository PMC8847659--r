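# Two-group differential expression with empirical-Bayes variance shrinkage,
# and the log-fold-change concordance check between the signature contrast and
# the SKP2 copy-number contrast.

#' Per-gene log fold changes and residual variances
#'
#' For each gene, the log2-scale mean difference between the two groups
#' (first factor level minus second), the pooled residual variance, and its
#' degrees of freedom nA + nB - 2.
#'
#' @param expr Genes x samples numeric matrix (log2 scale) with gene-id
#'   rownames.
#' @param labels Two-group label vector aligned with the columns of `expr`;
#'   samples with `NA` labels are dropped. Each group needs >= 2 samples.
#' @return A tibble with columns `gene_id`, `lfc`, `s2`, `df`; the squared
#'   standard-error multiplier 1/nA + 1/nB is attached as attribute
#'   `"contrast_var"`.
#' @export
fit_gene_lfc <- function(expr, labels) {
  if (ncol(expr) != length(labels)) abort("labels must align with expr columns")
  keep <- !is.na(labels)
  expr <- expr[, keep, drop = FALSE]
  labels <- droplevels(factor(labels[keep]))
  if (nlevels(labels) != 2) abort("labels must define exactly two groups")
  nA <- sum(labels == levels(labels)[1])
  nB <- sum(labels == levels(labels)[2])
  if (nA < 2 || nB < 2) abort("each group needs at least 2 samples")
  a <- expr[, labels == levels(labels)[1], drop = FALSE]
  b <- expr[, labels == levels(labels)[2], drop = FALSE]
  mA <- rowMeans(a)
  mB <- rowMeans(b)
  ssA <- rowSums((a - mA)^2)
  ssB <- rowSums((b - mB)^2)
  df <- nA + nB - 2L
  out <- tibble(
    gene_id = rownames(expr) %||% sprintf("gene_%d", seq_len(nrow(expr))),
    lfc = unname(mA - mB),
    s2 = unname((ssA + ssB) / df),
    df = df
  )
  attr(out, "contrast_var") <- 1 / nA + 1 / nB
  attr(out, "groups") <- levels(labels)
  out
}

# Solve trigamma(x) = y by Newton on the monotone decreasing trigamma,
# following the standard series start 0.5 + 1/y.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderated t statistics
#'
#' Shrinks per-gene residual variances toward a common prior and forms
#' moderated t statistics, following the standard empirical-Bayes model for
#' microarray linear fits: the prior (d0, s0^2) is estimated by method of
#' moments on log s2 via a scaled-F fit, the posterior variance is
#' `s_tilde^2 = (d0 * s0^2 + df * s2) / (d0 + df)`, the statistic is
#' `t_mod = lfc / sqrt(s_tilde^2 * contrast_var)` with `df + d0` degrees of
#' freedom, and p-values are adjusted by Benjamini-Hochberg. When the
#' log-variances show no excess spread beyond chi-square sampling noise, the
#' prior degrees of freedom are infinite and every gene receives the common
#' variance (full shrinkage); this is a valid limit, not an error.
#'
#' @param de Per-gene tibble from [fit_gene_lfc()] (columns `lfc`, `s2`, `df`).
#' @param contrast_var Squared standard-error multiplier of the contrast
#'   (1/nA + 1/nB for a two-group mean difference); defaults to the value
#'   attached by [fit_gene_lfc()].
#' @param d0,s0_sq Optional overrides of the estimated prior degrees of
#'   freedom / prior variance (e.g. `d0 = 0` recovers the ordinary t,
#'   `d0 = Inf` full shrinkage).
#' @return An object of class `ubistrat_de`: list with the per-gene `table`
#'   (`gene_id`, `lfc`, `s2`, `df`, `t_mod`, `p`, `p_adj`) and the globals
#'   `d0`, `s0_sq`, `contrast_var`.
#' @export
moderated_t <- function(de, contrast_var = NULL, d0 = NULL, s0_sq = NULL) {
  contrast_var <- contrast_var %||% attr(de, "contrast_var")
  if (is.null(contrast_var)) abort("`contrast_var` is required")
  check_scalar_pos(contrast_var, "contrast_var")
  if (nrow(de) < 10 && is.null(d0)) {
    abort("need at least 10 genes to estimate shrinkage hyperparameters")
  }
  s2 <- de$s2
  df <- de$df
  if (is.null(d0) || is.null(s0_sq)) {
    hp <- estimate_var_prior(s2, df)
    d0 <- d0 %||% hp$d0
    s0_sq <- s0_sq %||% hp$s0_sq
  }
  if (d0 == 0) {
    s_tilde <- s2
    df_total <- df
  } else if (is.infinite(d0)) {
    s_tilde <- rep(s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s_tilde <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  t_mod <- de$lfc / sqrt(s_tilde * contrast_var)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  tab <- tibble(
    gene_id = de$gene_id, lfc = de$lfc, s2 = s2, df = df,
    t_mod = t_mod, p = p, p_adj = benjamini_hochberg(p)
  )
  structure(list(table = tab, d0 = d0, s0_sq = s0_sq, contrast_var = contrast_var),
            class = "ubistrat_de")
}

# Method-of-moments fit of the scaled-F model for sample variances:
# log s2 has mean log s0^2 + digamma(df/2) - log(df/2) shifted by
# digamma(d0/2) - log(d0/2) and excess variance trigamma(d0/2) beyond the
# chi-square term trigamma(df/2).
estimate_var_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- s2 > 0 & df > 0
  if (sum(ok) < 2) abort("cannot estimate variance prior: too few positive variances")
  z <- log(s2[ok])
  d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Concordance of signature and SKP2 copy-number log fold changes
#'
#' Computes, gene by gene, (A) the log fold change between the
#' low- and high-ubiquitination signature groups (intermediate excluded) and
#' (B) the log fold change between SKP2 copy-number gain (level >= 1) and
#' normal-or-lost SKP2 (level <= 0), then reports the Spearman rank
#' correlation of the two all-gene LFC vectors. Both contrasts are oriented
#' toward increasing SKP2 activity (low ubiquitination stabilizes SKP2, as
#' does copy-number gain), so a signature that recapitulates the
#' transcriptional footprint of SKP2 dosage yields a positive correlation.
#'
#' @param expr Genes x samples matrix whose columns match `cohort$patient_id`.
#' @param cohort A stratified cohort (needs `ubiq_group` and `cn_skp2`).
#' @return An object of class `ubistrat_concordance`: `rho`, `p`, `n_genes`,
#'   and a per-gene tibble `lfc` with columns `gene_id`, `lfc_signature`,
#'   `lfc_skp2cn`.
#' @export
lfc_concordance <- function(expr, cohort) {
  if (!all(c("ubiq_group", "cn_skp2") %in% names(cohort))) {
    abort("cohort needs `ubiq_group` (run stratify_cohort) and `cn_skp2`")
  }
  idx <- match(cohort$patient_id, colnames(expr))
  if (anyNA(idx)) abort("expression matrix columns do not cover all patients")
  expr <- expr[, idx, drop = FALSE]

  lab_a <- ifelse(cohort$ubiq_group == "high", "high",
                  ifelse(cohort$ubiq_group == "low", "low", NA))
  lab_b <- ifelse(is.na(cohort$cn_skp2), NA,
                  ifelse(cohort$cn_skp2 >= 1, "skp2_high", "skp2_normlow"))
  if (sum(lab_a == "high", na.rm = TRUE) < 2 || sum(lab_a == "low", na.rm = TRUE) < 2 ||
      sum(lab_b == "skp2_high", na.rm = TRUE) < 2 ||
      sum(lab_b == "skp2_normlow", na.rm = TRUE) < 2) {
    abort("each contrast arm needs at least 2 samples")
  }
  de_a <- fit_gene_lfc(expr, factor(lab_a, levels = c("low", "high")))
  de_b <- fit_gene_lfc(expr, factor(lab_b, levels = c("skp2_high", "skp2_normlow")))
  sp <- spearman_cor(de_a$lfc, de_b$lfc)
  structure(list(
    rho = sp$rho, p = sp$p, n_genes = nrow(de_a),
    lfc = tibble(gene_id = de_a$gene_id,
                 lfc_signature = de_a$lfc, lfc_skp2cn = de_b$lfc)
  ), class = "ubistrat_concordance")
}
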