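# broom-style tidy()/glance() methods and compact print methods for the
# package's result objects.

#' @method tidy ubistrat_anova
#' @export
tidy.ubistrat_anova <- function(x, ...) {
  tibble(statistic = x$F, df_between = x$df_between, df_within = x$df_within,
         p.value = x$p)
}

#' @method glance ubistrat_anova
#' @export
glance.ubistrat_anova <- function(x, ...) tidy.ubistrat_anova(x)

#' @method tidy ubistrat_ttest
#' @export
tidy.ubistrat_ttest <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$t, df = x$df, p.value = x$p)
}

#' @method tidy ubistrat_spearman
#' @export
tidy.ubistrat_spearman <- function(x, ...) {
  tibble(estimate = x$rho, p.value = x$p, n = x$n)
}

#' @method tidy ubistrat_chisq
#' @export
tidy.ubistrat_chisq <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p,
         low_expected = x$low_expected)
}

#' @method tidy ubistrat_logrank
#' @export
tidy.ubistrat_logrank <- function(x, ...) {
  tibble(group = names(x$observed), observed = unname(x$observed),
         expected = unname(x$expected), n = x$n)
}

#' @method glance ubistrat_logrank
#' @export
glance.ubistrat_logrank <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p)
}

#' @method tidy ubistrat_nbfit
#' @export
tidy.ubistrat_nbfit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$std_errors),
         statistic = unname(x$z_values),
         p.value = unname(x$p_values),
         stars = p_stars(unname(x$p_values)))
}

#' @method glance ubistrat_nbfit
#' @export
glance.ubistrat_nbfit <- function(x, ...) {
  tibble(theta = x$theta, logLik = x$log_likelihood,
         converged = x$converged, nobs = x$n)
}

#' @method tidy ubistrat_de
#' @export
tidy.ubistrat_de <- function(x, ...) x$table

#' @method glance ubistrat_de
#' @export
glance.ubistrat_de <- function(x, ...) {
  tibble(d0 = x$d0, s0_sq = x$s0_sq, contrast_var = x$contrast_var,
         n_genes = nrow(x$table),
         n_significant = sum(x$table$p_adj < 0.05))
}

#' @method tidy ubistrat_concordance
#' @export
tidy.ubistrat_concordance <- function(x, ...) x$lfc

#' @method glance ubistrat_concordance
#' @export
glance.ubistrat_concordance <- function(x, ...) {
  tibble(rho = x$rho, p.value = x$p, n_genes = x$n_genes)
}

#' @method tidy ubistrat_ic50
#' @export
tidy.ubistrat_ic50 <- function(x, ...) x$pairwise

#' @method glance ubistrat_ic50
#' @export
glance.ubistrat_ic50 <- function(x, ...) {
  g <- tidy(x$anova)
  g$reference_drug <- x$reference_drug
  g
}

#' @method print ubistrat_anova
#' @export
print.ubistrat_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g on (%d, %d) df, p = %.4g\n",
              x$F, x$df_between, x$df_within, x$p))
  invisible(x)
}

#' @method print ubistrat_ttest
#' @export
print.ubistrat_ttest <- function(x, ...) {
  cat(sprintf("%s t test: t = %.4g, df = %.3g, p = %.4g (mean diff %.4g)\n",
              if (x$pooled) "Pooled" else "Welch", x$t, x$df, x$p, x$estimate))
  invisible(x)
}

#' @method print ubistrat_spearman
#' @export
print.ubistrat_spearman <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.4g, p = %.4g (n = %d)\n",
              x$rho, x$p, x$n))
  invisible(x)
}

#' @method print ubistrat_chisq
#' @export
print.ubistrat_chisq <- function(x, ...) {
  cat(sprintf("Chi-square independence: chi2 = %.4g, df = %d, p = %.4g%s\n",
              x$chi2, x$df, x$p,
              if (x$low_expected) " [expected cell < 5]" else ""))
  invisible(x)
}

#' @method print ubistrat_logrank
#' @export
print.ubistrat_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  print(tidy(x))
  invisible(x)
}

#' @method print ubistrat_nbfit
#' @export
print.ubistrat_nbfit <- function(x, ...) {
  cat(sprintf("Negative binomial GLM (log link), theta = %.4g%s\n",
              x$theta, if (x$converged) "" else " [NOT converged]"))
  print(tidy(x))
  invisible(x)
}

#' @method print ubistrat_de
#' @export
print.ubistrat_de <- function(x, ...) {
  cat(sprintf("Moderated-t differential expression: %d genes, d0 = %.4g, s0^2 = %.4g\n",
              nrow(x$table), x$d0, x$s0_sq))
  print(head(x$table[order(x$table$p), ], 10))
  invisible(x)
}

#' @method print ubistrat_concordance
#' @export
print.ubistrat_concordance <- function(x, ...) {
  cat(sprintf("LFC concordance (signature vs SKP2 CN): rho = %.4g, p = %.4g, %d genes\n",
              x$rho, x$p, x$n_genes))
  invisible(x)
}

#' @method print ubistrat_report
#' @export
print.ubistrat_report <- function(x, ...) {
  cat("ubistrat pipeline report\n")
  print(x$manifest, n = nrow(x$manifest))
  invisible(x)
}
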