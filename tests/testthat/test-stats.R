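test_that("one-way ANOVA reproduces the hand decomposition and conventions", {
  # identical group means: no between-group variance
  av0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(av0$F, 0)
  expect_equal(av0$p, 1)
  # hand decomposition: SSB = 16, SSW = 1.5 -> F = 16 on (2, 3) df
  av <- one_way_anova(1:6, rep(c("a", "b", "c"), each = 2))
  expect_equal(av$F, 16)
  expect_identical(c(av$df_between, av$df_within), c(2L, 3L))
  expect_equal(av$p, pf(16, 2, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(av$p, 0.025, tolerance = 1e-2)
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("one-way ANOVA matches aov and equals t-squared for two groups", {
  withr::local_seed(42)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    g <- factor(rep(seq_len(k), times = sample(3:8, k, replace = TRUE)))
    y <- rnorm(length(g), mean = as.integer(g) * 0.3)
    ours <- one_way_anova(y, g)
    ref <- summary(stats::aov(y ~ g))[[1]]
    expect_equal(ours$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(ours$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    if (k == 2) {
      tt <- stats::t.test(y[g == 1], y[g == 2], var.equal = TRUE)
      expect_equal(ours$F, unname(tt$statistic)^2, tolerance = 1e-10)
    }
  }
})

test_that("Welch t test follows the closed form and degenerate conventions", {
  tt0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)
  tt <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1 / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.288, tolerance = 1e-2)
  # constant samples: equal means t = 0; unequal means are degenerate
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p, 1)
  expect_error(welch_t_test(c(0, 0), c(1, 1)), "degenerate variance")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  # pooled flag reproduces the Student form
  x <- c(1.2, 0.8, 1.5, 0.3); y <- c(2.2, 1.4, 2.9)
  expect_equal(welch_t_test(x, y, pooled = TRUE)$t,
               unname(stats::t.test(x, y, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
})

test_that("Spearman correlation handles ranks, ties and monotone transforms", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_cor(1:5, -(1:5))$rho, -1)
  sp <- spearman_cor(c(1, 2, 3), c(3, 1, 2))
  expect_equal(sp$rho, -0.5)   # Sum d^2 = 6 -> 1 - 36/24
  withr::local_seed(8)
  x <- rnorm(40); y <- rnorm(40) + 0.5 * x
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman_cor(x, y^3 + 10)$rho, base$rho, tolerance = 1e-12)
  expect_equal(base$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero rank variance")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("Benjamini-Hochberg is the step-up adjustment and stays monotone", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.05), 0.05)
  withr::local_seed(12)
  for (i in 1:5) {
    p <- runif(30)
    adj <- benjamini_hochberg(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("chi-square independence matches the direct O-E oracle", {
  cs0 <- chi_square_independence(matrix(10, 2, 2))
  expect_equal(cs0$chi2, 0)
  expect_equal(cs0$p, 1)
  cs <- chi_square_independence(matrix(c(20, 10, 10, 20), 2))
  expect_equal(cs$chi2, 20 / 3, tolerance = 1e-10)  # all expected cells 15
  expect_identical(cs$df, 1L)
  expect_equal(cs$p, 0.0098, tolerance = 1e-2)
  withr::local_seed(77)
  for (i in 1:10) {
    tab <- matrix(rpois(12, 20) + 1, 3, 4)
    ours <- chi_square_independence(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    oracle <- sum((tab - expected)^2 / expected)
    expect_equal(ours$chi2, oracle, tolerance = 1e-12)
    expect_equal(rowSums(ours$expected), rowSums(tab), tolerance = 1e-9)
  }
  expect_error(chi_square_independence(matrix(c(1, 0, 0, 0), 2)), "zero marginal")
  expect_true(chi_square_independence(matrix(c(3, 2, 2, 3), 2))$low_expected)
})

test_that("significance stars follow the conventional thresholds", {
  expect_identical(p_stars(c(0.0005, 0.001, 0.0099, 0.01, 0.049, 0.05, 1)),
                   c("***", "**", "**", "*", "*", "", ""))
  expect_identical(p_stars(0.03), "*")
})
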