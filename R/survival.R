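# Kaplan-Meier estimation and log-rank testing (thin wrappers around the
# survival package, returning tidy structures with the conventions the
# pipeline relies on).

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function. Censoring at an event
#' time is processed after the deaths at that time (the standard convention).
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A tibble of class `ubistrat_km` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, covering every distinct observed time.
#' @export
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
#' surv_at(km, 1)  # 2/3
km_estimate <- function(times, events) {
  if (length(times) == 0) abort("empty input")
  if (length(times) != length(events)) abort("`times` and `events` lengths differ")
  if (any(!is.finite(times)) || any(times < 0)) abort("times must be finite and >= 0")
  if (!all(events %in% c(0, 1))) abort("events must be 0/1")
  sf <- survfit(Surv(times, events) ~ 1)
  out <- tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, survival = sf$surv
  )
  class(out) <- c("ubistrat_km", class(out))
  out
}

#' Survival probability at a time point
#'
#' Step-function lookup on a [km_estimate()] curve: the survival just after
#' `t` (1 before the first event).
#'
#' @param km A `ubistrat_km` tibble.
#' @param t Time point(s).
#' @return Numeric survival probabilities.
#' @export
surv_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (length(i) == 0) 1 else km$survival[max(i)]
  }, numeric(1))
}

#' Log-rank test across survival groups
#'
#' The k-sample log-rank test: at each distinct event time the expected
#' per-group events come from the hypergeometric mean, and the chi-square
#' statistic (df = k - 1) aggregates observed-minus-expected with the
#' standard covariance form.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group labels (k >= 2 levels after dropping `NA`).
#' @return An object of class `ubistrat_logrank` with `chi2`, `df`, `p`,
#'   and per-group `observed` / `expected` event counts.
#' @export
logrank_test <- function(times, events, groups) {
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]; events <- events[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (sum(events) == 0) abort("no events observed")
  sd <- survdiff(Surv(times, events) ~ groups)
  k <- nlevels(groups)
  chi2 <- unname(sd$chisq)
  df <- k - 1L
  structure(list(
    chi2 = chi2, df = df,
    p = pchisq(chi2, df = df, lower.tail = FALSE),
    observed = setNames(as.numeric(sd$obs), levels(groups)),
    expected = setNames(as.numeric(sd$exp), levels(groups)),
    n = as.numeric(sd$n)
  ), class = "ubistrat_logrank")
}

#' Survival comparison between ubiquitination groups
#'
#' Convenience wrapper: runs the log-rank test on a stratified cohort,
#' comparing high vs low ubiquitination with intermediate patients excluded
#' (`three_group = FALSE`, the default) or keeping intermediate as its own
#' stratum (`three_group = TRUE`, as used with the expression-based
#' three-group signature). Unclassified patients are always excluded.
#'
#' @param cohort A stratified cohort with `os_time`, `os_event`, `ubiq_group`.
#' @param three_group Keep the intermediate group as a stratum.
#' @return A `ubistrat_logrank` object; the per-group KM curves are attached
#'   as attribute `"curves"` (a tibble with a `ubiq_group` column).
#' @export
survival_by_group <- function(cohort, three_group = FALSE) {
  need <- c("os_time", "os_event", "ubiq_group")
  if (!all(need %in% names(cohort))) {
    abort("cohort needs os_time, os_event and ubiq_group columns")
  }
  keep_levels <- if (three_group) c("high", "intermediate", "low") else c("high", "low")
  sub <- cohort[cohort$ubiq_group %in% keep_levels, ]
  res <- logrank_test(sub$os_time, sub$os_event,
                      factor(sub$ubiq_group, levels = keep_levels))
  curves <- lapply(keep_levels, function(g) {
    gg <- sub[sub$ubiq_group == g, ]
    if (nrow(gg) == 0) return(NULL)
    km <- km_estimate(gg$os_time, gg$os_event)
    km$ubiq_group <- g
    as_tibble(km)
  })
  attr(res, "curves") <- bind_rows(curves)
  res
}
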