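test_that("copy-number classifier agrees with the sign oracle on all 25 level pairs", {
  pairs <- expand.grid(fzr1 = -2:2, usp = -2:2)
  got <- classify_cn(pairs$fzr1, pairs$usp)
  oracle <- c("low", "intermediate", "high")[sign(pairs$fzr1 - pairs$usp) + 2]
  expect_identical(as.character(got), oracle)
  # worked example: USP level 0, FZR1 level -1 -> low ubiquitination
  expect_identical(as.character(classify_cn(-1, 0)), "low")
})

test_that("copy-number classifier is antisymmetric and flags missing input", {
  pairs <- expand.grid(a = -2:2, b = -2:2)
  ab <- classify_cn(pairs$a, pairs$b)
  ba <- classify_cn(pairs$b, pairs$a)
  expect_identical(ab == "high", ba == "low")
  expect_identical(ab == "intermediate", ba == "intermediate")
  expect_identical(as.character(classify_cn(NA, 0)), "unclassified")
  expect_identical(as.character(classify_cn(1, NA)), "unclassified")
  expect_error(classify_cn(3, 0), "3")
  expect_error(classify_cn(0, -4), "-4")
})

test_that("expression classifier applies the median rule with literal ties", {
  expect_identical(as.character(classify_expression(5, 7, 6, 6)), "low")
  expect_identical(as.character(classify_expression(7, 5, 6, 6)), "high")
  expect_identical(as.character(classify_expression(7, 7, 6, 6)), "intermediate")
  # exactly at both medians: "at or below" applies to both, so intermediate
  expect_identical(as.character(classify_expression(6, 6, 6, 6)), "intermediate")
  expect_error(classify_expression(NA, 1, 0, 0), "finite")
})

test_that("expression classifier is invariant to joint strictly monotone transforms", {
  withr::local_seed(11)
  for (i in 1:5) {
    f <- rnorm(50); u <- rnorm(50)
    base <- classify_expression(f, u, median(f), median(u))
    tf <- exp(f); tu <- u^3
    trans <- classify_expression(tf, tu, median(tf), median(tu))
    expect_identical(base, trans)
  }
})

test_that("IHC subtype assignment follows the receptor definitions and is total", {
  expect_identical(as.character(assign_subtype("positive", "negative", "positive")),
                   "luminal")
  expect_identical(as.character(assign_subtype("negative", "negative", "positive")),
                   "her2")
  expect_identical(as.character(assign_subtype("negative", "negative", "negative")),
                   "tnbc")
  expect_identical(as.character(assign_subtype("negative", "positive", "negative")),
                   "other")
  combos <- expand.grid(er = c("positive", "negative", "unknown"),
                        pr = c("positive", "negative", "unknown"),
                        her2 = c("positive", "negative", "unknown"),
                        stringsAsFactors = FALSE)
  st <- assign_subtype(combos$er, combos$pr, combos$her2)
  expect_no_na(st)
  expect_true(all(st[combos$er == "unknown"] == "other"))
})

test_that("cohort stratification matches the independent-marginals convolution", {
  cfg <- sim_config(n_patients = 20000, seed = 5)
  cohort <- stratify_cohort(simulate_cohort(cfg))
  m <- cfg$cn_marginals$fzr1
  p_equal <- sum(m^2)              # P(fzr1 == usp10) under independence
  p_high <- (1 - p_equal) / 2      # symmetric marginal
  freq <- table(cohort$ubiq_group) / nrow(cohort)
  expect_lt(abs(freq[["intermediate"]] - p_equal), 0.02)
  expect_lt(abs(freq[["high"]] - p_high), 0.02)
  expect_lt(abs(freq[["low"]] - p_high), 0.02)
  expect_identical(sum(group_counts(cohort)$n), nrow(cohort))
})

test_that("equal copy numbers give a fully intermediate cohort and NAs are kept", {
  cohort <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:20),
    er = "positive", pr = "negative", her2 = "negative",
    cn_fzr1 = rep(0L, 20), cn_usp10 = rep(0L, 20),
    cn_usp13 = 0L, cn_skp2 = 0L
  )
  out <- stratify_cohort(cohort)
  expect_true(all(out$ubiq_group == "intermediate"))

  cohort$cn_fzr1[3] <- NA
  out <- stratify_cohort(cohort)
  expect_identical(nrow(out), 20L)  # unclassified rows retained
  expect_identical(as.character(out$ubiq_group[3]), "unclassified")
  expect_identical(attr(out, "n_unclassified"), 1L)
})

test_that("expression-mode stratification of independent genes gives quadrant proportions", {
  withr::local_seed(21)
  n <- 4000
  cohort <- tibble::tibble(
    patient_id = sprintf("P%05d", 1:n),
    er = "positive", pr = "negative", her2 = "negative"
  )
  expr <- matrix(rnorm(8 * n), 8, n,
                 dimnames = list(c("FZR1", "USP10", "USP13", "SKP2",
                                   paste0("G", 1:4)), cohort$patient_id))
  out <- stratify_cohort(cohort, mode = "expression", expr = expr)
  freq <- table(out$ubiq_group) / n
  expect_lt(abs(freq[["high"]] - 0.25), 0.03)
  expect_lt(abs(freq[["low"]] - 0.25), 0.03)
  expect_lt(abs(freq[["intermediate"]] - 0.50), 0.03)
  expect_error(stratify_cohort(cohort, mode = "expression"), "requires")
})
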