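# SKP2-ubiquitination signature classifiers and IHC subtype assignment.

#' Classify SKP2-ubiquitination group from copy-number levels
#'
#' The two-gene signature compares the discrete copy-number level of FZR1
#' (the APC/C co-activator that directs SKP2 ubiquitination) against that of
#' a deubiquitinase (USP10 or USP13). More ligase dosage than deubiquitinase
#' dosage implies more SKP2 ubiquitination:
#' \itemize{
#'   \item FZR1 level > USP level: \code{"high"} ubiquitination
#'         (expected low SKP2 protein, high p27),
#'   \item equal levels: \code{"intermediate"},
#'   \item FZR1 level < USP level: \code{"low"} ubiquitination
#'         (expected high SKP2, low p27).
#' }
#' A missing level on either gene yields \code{"unclassified"}.
#'
#' @param fzr1_level,usp_level Integer vectors of copy-number levels in
#'   \{-2, -1, 0, 1, 2\} (cBioPortal convention); `NA` allowed.
#' @return Factor with levels high/intermediate/low/unclassified.
#' @export
#' @examples
#' classify_cn(-1, 0)  # low: ligase lost relative to deubiquitinase
#' classify_cn(c(0, 2), c(0, -2))
classify_cn <- function(fzr1_level, usp_level) {
  check_cn(fzr1_level, "fzr1_level")
  check_cn(usp_level, "usp_level")
  if (length(fzr1_level) != length(usp_level)) {
    abort("`fzr1_level` and `usp_level` must have equal length")
  }
  d <- fzr1_level - usp_level
  out <- rep("unclassified", length(d))
  out[!is.na(d) & d > 0] <- "high"
  out[!is.na(d) & d == 0] <- "intermediate"
  out[!is.na(d) & d < 0] <- "low"
  factor(out, levels = ubiq_levels)
}

#' Classify SKP2-ubiquitination group from expression medians
#'
#' Expression-based variant of the signature for datasets without copy-number
#' calls. A sample with FZR1 expression at or below the dataset-wide FZR1
#' median and USP10 expression above the USP10 median is called
#' \code{"low"} ubiquitination; the mirror image is \code{"high"}; all other
#' samples are \code{"intermediate"}. The "at or below" tie rule is applied
#' literally, so a sample exactly at both medians is intermediate.
#'
#' @param fzr1_expr,usp10_expr Numeric expression values (any common scale).
#' @param fzr1_median,usp10_median Medians computed over the full dataset
#'   being classified.
#' @return Factor with levels high/intermediate/low/unclassified.
#' @export
classify_expression <- function(fzr1_expr, usp10_expr, fzr1_median, usp10_median) {
  vals <- c(fzr1_expr, usp10_expr, fzr1_median, usp10_median)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort("expression values and medians must be finite numerics")
  }
  if (length(fzr1_expr) != length(usp10_expr)) {
    abort("`fzr1_expr` and `usp10_expr` must have equal length")
  }
  low <- fzr1_expr <= fzr1_median & usp10_expr > usp10_median
  high <- usp10_expr <= usp10_median & fzr1_expr > fzr1_median
  out <- rep("intermediate", length(fzr1_expr))
  out[low] <- "low"
  out[high] <- "high"
  factor(out, levels = ubiq_levels)
}

#' Assign an IHC-based breast-cancer subtype
#'
#' Subtypes follow the immunohistochemistry definitions: ER-positive is
#' luminal; ER-negative, PR-negative, HER2-positive is HER2; triple-negative
#' is TNBC; any other combination (including unknown markers) is "other".
#'
#' @param er,pr,her2 Character vectors with values `"positive"`, `"negative"`
#'   or `"unknown"`.
#' @return Factor with levels luminal/her2/tnbc/other.
#' @export
#' @examples
#' assign_subtype("positive", "negative", "positive")  # luminal
assign_subtype <- function(er, pr, her2) {
  ok <- c("positive", "negative", "unknown")
  for (v in list(er = er, pr = pr, her2 = her2)) {
    if (!all(v %in% ok)) abort("receptor statuses must be positive/negative/unknown")
  }
  n <- max(length(er), length(pr), length(her2))
  er <- rep_len(er, n); pr <- rep_len(pr, n); her2 <- rep_len(her2, n)
  out <- rep("other", n)
  out[er == "positive"] <- "luminal"
  out[er == "negative" & pr == "negative" & her2 == "positive"] <- "her2"
  out[er == "negative" & pr == "negative" & her2 == "negative"] <- "tnbc"
  factor(out, levels = subtype_levels)
}

#' Stratify a cohort by the SKP2-ubiquitination signature
#'
#' Adds a `ubiq_group` column to the cohort using either a copy-number mode
#' (FZR1 vs USP10 or USP13) or the expression-median rule (which requires an
#' expression matrix containing `FZR1` and `USP10` rows). Samples that cannot
#' be classified (missing copy-number calls) are flagged `"unclassified"`,
#' never dropped. A `subtype` column is derived from the receptor statuses if
#' not already present. Per-(group x subtype) counts are attached as the
#' `"counts"` attribute and available via [group_counts()].
#'
#' @param cohort A cohort data frame (see [simulate_cohort()] / [read_cohort()]).
#' @param mode `"cn_usp10"` (default), `"cn_usp13"`, or `"expression"`.
#' @param expr Optional genes x samples expression matrix (required for
#'   `mode = "expression"`); columns must match `cohort$patient_id`.
#' @return The cohort as a tibble with `ubiq_group` (and `subtype`) columns.
#' @export
stratify_cohort <- function(cohort, mode = c("cn_usp10", "cn_usp13", "expression"),
                            expr = NULL) {
  mode <- match.arg(mode)
  cohort <- as_tibble(cohort)
  if (!"subtype" %in% names(cohort)) {
    if (!all(c("er", "pr", "her2") %in% names(cohort))) {
      abort("cohort needs either a `subtype` column or er/pr/her2 statuses")
    }
    cohort$subtype <- assign_subtype(cohort$er, cohort$pr, cohort$her2)
  }
  if (mode %in% c("cn_usp10", "cn_usp13")) {
    usp_col <- sub("cn_", "cn_", mode)
    if (!all(c("cn_fzr1", usp_col) %in% names(cohort))) {
      abort(sprintf("cohort lacks columns cn_fzr1/%s required for mode '%s'", usp_col, mode))
    }
    cohort$ubiq_group <- classify_cn(cohort$cn_fzr1, cohort[[usp_col]])
  } else {
    if (is.null(expr)) abort("expression mode requires an expression matrix `expr`")
    need <- c("FZR1", "USP10")
    if (!all(need %in% rownames(expr))) {
      abort("expression matrix must contain FZR1 and USP10 rows")
    }
    idx <- match(cohort$patient_id, colnames(expr))
    if (anyNA(idx)) abort("expression matrix columns do not cover all patients")
    fz <- expr["FZR1", idx]
    us <- expr["USP10", idx]
    cohort$ubiq_group <- classify_expression(fz, us, median(fz), median(us))
  }
  counts <- count(cohort, .data$ubiq_group, .data$subtype, .drop = FALSE)
  attr(cohort, "counts") <- counts
  n_uncl <- sum(cohort$ubiq_group == "unclassified")
  attr(cohort, "n_unclassified") <- n_uncl
  cohort
}

#' Per-(group x subtype) counts from a stratified cohort
#'
#' @param cohort A cohort returned by [stratify_cohort()].
#' @return A tibble with columns `ubiq_group`, `subtype`, `n`.
#' @export
group_counts <- function(cohort) {
  counts <- attr(cohort, "counts")
  if (is.null(counts)) {
    if (!"ubiq_group" %in% names(cohort)) abort("cohort has no `ubiq_group` column")
    counts <- count(as_tibble(cohort), .data$ubiq_group, .data$subtype, .drop = FALSE)
  }
  counts
}
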