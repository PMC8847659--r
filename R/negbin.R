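# Negative binomial (NB2) regression of count outcomes on the signature
# group, fit by alternating IRLS for the coefficients and Newton's method on
# the digamma score for the dispersion.

nb_loglik <- function(y, mu, theta) {
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# Profile score and its derivative in theta (beta held fixed).
nb_theta_score <- function(theta, y, mu) {
  sum(digamma(y + theta) - digamma(theta) + log(theta) + 1 -
        log(theta + mu) - (y + theta) / (theta + mu))
}

nb_theta_score_deriv <- function(theta, y, mu) {
  sum(trigamma(y + theta) - trigamma(theta) + 1 / theta -
        1 / (theta + mu) + (y - mu) / (theta + mu)^2)
}

# Newton update for theta with step-halving and positivity guard.
nb_update_theta <- function(theta, y, mu, max_iter = 50L) {
  for (i in seq_len(max_iter)) {
    sc <- nb_theta_score(theta, y, mu)
    dsc <- nb_theta_score_deriv(theta, y, mu)
    if (!is.finite(sc) || !is.finite(dsc) || dsc == 0) break
    step <- sc / dsc
    new <- theta - step
    halvings <- 0L
    while ((new <= 0 || !is.finite(nb_theta_score(new, y, mu))) && halvings < 30L) {
      step <- step / 2
      new <- theta - step
      halvings <- halvings + 1L
    }
    if (new <= 0) break
    if (abs(new - theta) < 1e-10 * (theta + 1e-10)) {
      theta <- new
      break
    }
    theta <- new
    if (theta > 1e6) break
  }
  theta
}

# IRLS for beta at fixed theta (expected-information weights mu/(1 + mu/theta)).
nb_irls_beta <- function(X, y, beta, theta, max_iter = 25L, tol = 1e-10) {
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    w <- mu / (1 + mu / theta)
    z <- eta + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  beta
}

#' Negative binomial regression of counts on ubiquitination group
#'
#' Fits a log-link NB2 GLM `count ~ group` with the high-ubiquitination group
#' as the baseline level, so the reported `intermediate` and `low`
#' coefficients are log-ratios of expected counts relative to the high group
#' (positive = more positive lymph nodes than the high group). Coefficients
#' and dispersion are estimated by alternating IRLS for the coefficients
#' given theta and Newton's method on the profile score for theta given the
#' coefficients, until the log-likelihood change falls below `tol` (at most
#' `max_outer` rounds). Standard errors come from the expected information
#' at convergence, Wald z statistics use the normal reference. Equidispersed
#' or underdispersed data push theta to the Poisson limit; theta is then
#' capped at 1e6 with a warning.
#'
#' @param counts Non-negative integer response (>= 10 observations, not all
#'   zero).
#' @param group Factor of group labels; a `"high"` level, when present, is
#'   used as the baseline. Intercept-only fits (single level) are allowed.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_outer Maximum outer (beta, theta) rounds.
#' @return An object of class `ubistrat_nbfit`: named `coefficients`,
#'   `std_errors`, `z_values`, `p_values`, `theta`, `log_likelihood`,
#'   `converged`, `loglik_trace`, `n`.
#' @export
#' @examples
#' fit <- fit_negbin_glm(rnbinom(200, size = 0.5, mu = 2),
#'                       rep(c("high", "low"), 100))
#' tidy(fit)
fit_negbin_glm <- function(counts, group = NULL, tol = 1e-8, max_outer = 100L) {
  y <- counts
  if (anyNA(y) || any(y < 0) || any(y != floor(y))) {
    abort("`counts` must be non-negative integers without NA")
  }
  if (all(y == 0)) abort("all counts are zero; the NB mean is degenerate")
  if (is.null(group)) group <- rep("all", length(y))
  if (length(group) != length(y)) abort("`group` must match `counts` in length")
  group <- droplevels(factor(group))
  if (nlevels(group) > 1L && length(y) < 10) {
    abort("need at least 10 observations to fit group contrasts")
  }
  if (length(y) < 3) abort("need at least 3 observations")
  if ("high" %in% levels(group)) group <- stats::relevel(group, ref = "high")
  if (nlevels(group) == 1L) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- model.matrix(~group)
    colnames(X) <- sub("^group", "", colnames(X))
  }

  # Initialize with a Poisson fit; theta by method of moments on its
  # Pearson residuals.
  pois <- stats::glm.fit(X, y, family = stats::poisson())
  beta <- pois$coefficients
  mu <- exp(drop(X %*% beta))
  denom <- sum((y - mu)^2 - mu)
  theta <- if (denom > 0) sum(mu^2) / denom else 1e4
  theta <- min(max(theta, 1e-3), 1e6)

  ll <- nb_loglik(y, mu, theta)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    beta <- nb_irls_beta(X, y, beta, theta)
    mu <- exp(drop(X %*% beta))
    theta <- nb_update_theta(theta, y, mu)
    if (theta >= 1e6) {
      theta <- 1e6
      warn("counts not overdispersed; theta capped at 1e6 (Poisson limit)")
      beta <- nb_irls_beta(X, y, beta, theta)
      mu <- exp(drop(X %*% beta))
      converged <- TRUE
      trace <- c(trace, nb_loglik(y, mu, theta))
      break
    }
    ll_new <- nb_loglik(y, mu, theta)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  w <- mu / (1 + mu / theta)
  info <- crossprod(X, X * w)
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  nm <- colnames(X)
  structure(list(
    coefficients = setNames(as.numeric(beta), nm),
    std_errors = setNames(as.numeric(se), nm),
    z_values = setNames(as.numeric(z), nm),
    p_values = setNames(as.numeric(p), nm),
    theta = theta,
    log_likelihood = nb_loglik(y, mu, theta),
    converged = converged,
    loglik_trace = trace,
    n = length(y)
  ), class = "ubistrat_nbfit")
}
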