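# Classical univariate tests used throughout the pipeline, with the
# degenerate-input conventions the pipeline relies on made explicit.

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance (between/within
#' decomposition, F reference distribution). Degenerate conventions: if both
#' the between- and within-group sums of squares are zero, F = 0 and p = 1;
#' if only the within-group sum of squares is zero, F = Inf and p = 0.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`; every group needs at
#'   least two observations.
#' @return An object of class `ubistrat_anova` with elements `F`,
#'   `df_between`, `df_within`, `p`, and `group_means`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
one_way_anova <- function(values, groups) {
  if (length(values) != length(groups)) abort("`values` and `groups` lengths differ")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least 2 groups")
  if (any(tab < 2)) {
    abort(sprintf("group '%s' has fewer than 2 observations", names(tab)[tab < 2][1]))
  }
  k <- length(tab)
  N <- length(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(tab * (means - mean(values))^2)
  ssw <- sum((values - means[as.character(groups)])^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = f, df_between = df1, df_within = df2, p = p,
                 group_means = as.list(means)),
            class = "ubistrat_anova")
}

#' Two-sample t test (Welch by default)
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of freedom
#' and a two-tailed p-value; `pooled = TRUE` restores the classical
#' pooled-variance Student form. If both samples have zero variance, equal
#' means give t = 0 and p = 1, while unequal means are rejected as a
#' degenerate-variance error.
#'
#' @param x,y Numeric samples, each with at least two values.
#' @param pooled Use the pooled-variance Student t instead of Welch.
#' @return An object of class `ubistrat_ttest` with `t`, `df`, `p`,
#'   `estimate` (mean difference x - y).
#' @export
welch_t_test <- function(x, y, pooled = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("each sample needs at least 2 values")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(structure(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                            estimate = 0, pooled = pooled),
                       class = "ubistrat_ttest"))
    }
    abort("degenerate variance: both samples constant with unequal means")
  }
  ht <- t.test(x, y, var.equal = pooled)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, estimate = mean(x) - mean(y), pooled = pooled),
            class = "ubistrat_ttest")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data. The p-value uses the
#' t approximation t = rho * sqrt((n - 2) / (1 - rho^2)) with n - 2 degrees
#' of freedom (two-tailed); for |rho| = 1 the p-value is reported as 0.
#'
#' @param x,y Equal-length numeric vectors of length >= 3.
#' @return An object of class `ubistrat_spearman` with `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman_cor(c(1, 2, 3), c(3, 1, 2))
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` lengths differ")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0) {
    abort("undefined under zero rank variance (constant input)")
  }
  rho <- cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p = p, n = n), class = "ubistrat_spearman")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (capped at 1, monotone in p-rank).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be numeric in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Chi-square test of independence
#'
#' Pearson chi-square on a contingency table without continuity correction.
#' A `low_expected` flag marks tables where any expected cell count falls
#' below 5 (the usual validity caveat).
#'
#' @param table Non-negative integer matrix, at least 2 x 2, with strictly
#'   positive row and column sums.
#' @return An object of class `ubistrat_chisq` with `chi2`, `df`, `p`,
#'   `expected`, `low_expected`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) abort("table must be at least 2 x 2")
  if (any(table < 0) || anyNA(table)) abort("table must be non-negative and complete")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero marginal: every row and column needs a positive total")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, expected = ht$expected,
                 low_expected = any(ht$expected < 5)),
            class = "ubistrat_chisq")
}
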