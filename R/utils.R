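# Internal helpers shared across modules.

#' Significance stars for p-values
#'
#' Maps p-values to the conventional significance annotation: `***` for
#' p < 0.001, `**` for 0.001 <= p < 0.01, `*` for 0.01 <= p < 0.05, and an
#' empty string otherwise.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of the same length.
#' @export
#' @examples
#' p_stars(c(0.0001, 0.005, 0.03, 0.2))
p_stars <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep("", length(p))
  out[p < 0.05]  <- "*"
  out[p < 0.01]  <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# Validate a probability vector: numeric, non-negative, sums to 1 within 1e-9.
check_prob_vector <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    abort(sprintf("`%s` must be a non-negative numeric probability vector", what))
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("`%s` must sum to 1 (got %.12f)", what, sum(p)))
  }
  invisible(p)
}

check_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive scalar", what))
  }
  invisible(x)
}

# CN levels follow the cBioPortal discrete convention: -2 deep loss, -1 shallow
# loss, 0 diploid, 1 low-level gain, 2 high-level amplification.
cn_levels <- -2:2

check_cn <- function(x, what) {
  bad <- which(!is.na(x) & !(x %in% cn_levels))
  if (length(bad)) {
    abort(sprintf(
      "`%s` contains copy-number level(s) outside {-2,...,2}: value %s at position %d",
      what, format(x[bad[1]]), bad[1]
    ))
  }
  invisible(x)
}

ubiq_levels <- c("high", "intermediate", "low", "unclassified")
subtype_levels <- c("luminal", "her2", "tnbc", "other")

# Deterministic sub-stream seeds derived from a master seed, kept within the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}
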