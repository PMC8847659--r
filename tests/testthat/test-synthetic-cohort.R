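test_that("dispersion derivation inverts the NB variance identity", {
  expect_equal(derive_theta(1.80, 14.52), 1.80^2 / (14.52 - 1.80), tolerance = 1e-12)
  expect_equal(derive_theta(1.80, 14.52), 0.2547, tolerance = 1e-3)
  expect_equal(derive_theta(2.00, 16.84), 0.2695, tolerance = 1e-3)
  expect_error(derive_theta(1, 1), "not overdispersed")
  expect_error(derive_theta(2, 1.5), "not overdispersed")
})

test_that("identical config and seed give bit-identical cohorts and expression", {
  cfg <- small_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  ea <- simulate_expression(cfg, a)
  eb <- simulate_expression(cfg, b)
  expect_identical(ea, eb)
  # different seed changes the draw
  expect_false(identical(a, simulate_cohort(cfg, seed = 999)))
})

test_that("configuration invariants are enforced", {
  expect_error(simulate_cohort(sim_config(n_patients = 5)), "cohort too small")
  expect_error(sim_config(cn_marginals = list(fzr1 = c(0.5, 0.5, 0.1, 0, 0),
                                              usp10 = rep(0.2, 5),
                                              usp13 = rep(0.2, 5),
                                              skp2 = rep(0.2, 5))),
               "sum to 1")
  expect_error(sim_config(p27_sd = 0), "positive")
  expect_error(sim_config(nb_theta = -1), "positive")
  expect_error(sim_config(subtype_proportions = c(0.8, 0.3, 0.2)), "<= 1")
})

test_that("copy-number marginals are reproduced within 2 percent at n = 50000", {
  cfg <- sim_config(n_patients = 50000, seed = 33)
  cohort <- simulate_cohort(cfg)
  for (g in c("cn_fzr1", "cn_usp10", "cn_usp13", "cn_skp2")) {
    emp <- tabulate(cohort[[g]] + 3, nbins = 5) / nrow(cohort)
    expect_true(all(abs(emp - cfg$cn_marginals$fzr1) < 0.02), info = g)
  }
})

test_that("node counts have the planted NB mean and variance", {
  cfg <- sim_config(n_patients = 50000, seed = 7,
                    nb_coefficients = c(0.43, 0.29, 0.58), nb_theta = 0.25,
                    group_scope = "all")
  cohort <- stratify_cohort(simulate_cohort(cfg))
  high <- cohort$positive_nodes[cohort$ubiq_group == "high"]
  mu <- exp(0.43)
  expect_lt(abs(mean(high) - mu), 0.05)
  expect_lt(abs(var(high) / (mu + mu^2 / 0.25) - 1), 0.10)
  low <- cohort$positive_nodes[cohort$ubiq_group == "low"]
  mu_low <- exp(0.43 + 0.58)
  expect_lt(abs(mean(low) - mu_low), 0.10)
})

test_that("censoring hits the configured fraction and survival times are valid", {
  cfg <- sim_config(n_patients = 5000, seed = 9, censor_fraction_target = 0.55)
  cohort <- simulate_cohort(cfg)
  expect_lt(abs(mean(cohort$os_event == 0) - 0.55), 0.05)
  expect_true(all(cohort$os_time >= 0))
  # no censoring requested -> every patient has an event
  cfg0 <- sim_config(n_patients = 500, seed = 9, censor_fraction_target = 0)
  expect_true(all(simulate_cohort(cfg0)$os_event == 1))
})

test_that("a null configuration carries no group signal (uniform ANOVA p across seeds)", {
  ps <- vapply(1:200, function(s) {
    cfg <- sim_config(n_patients = 300, seed = 40000 + s,
                      p27_effect = 0, hazard_ratio_low_vs_high = 1,
                      stage_grade_shift = 0,
                      nb_coefficients = c(0.43, 0, 0), group_scope = "all")
    cohort <- stratify_cohort(simulate_cohort(cfg))
    keep <- cohort$ubiq_group != "unclassified"
    one_way_anova(cohort$p27[keep], droplevels(cohort$ubiq_group[keep]))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("expression simulation plants the latent factor and tracks copy number", {
  cfg <- sim_config(n_patients = 2000, n_genes = 400, seed = 13,
                    frac_responsive = 0.3, expr_effect_sd = 1)
  cohort <- simulate_cohort(cfg)
  expr <- simulate_expression(cfg, cohort)
  expect_identical(dim(expr), c(400L, 2000L))
  expect_identical(rownames(expr)[1:4], c("FZR1", "USP10", "USP13", "SKP2"))
  expect_true(all(is.finite(expr)))
  # signature-gene expression increases with own copy-number level
  for (pair in list(c("FZR1", "cn_fzr1"), c("USP10", "cn_usp10"))) {
    expect_gt(cor(expr[pair[1], ], cohort[[pair[2]]]), 0.2)
  }
  # some genes respond strongly to latent SKP2 activity
  cors <- abs(cor(t(expr[5:400, ]), cohort$latent_skp2))
  expect_gt(mean(cors > 0.3), 0.1)
  expect_error(simulate_expression(cfg, dplyr::select(cohort, -latent_skp2)),
               "latent_skp2")
})

test_that("degenerate expression sizes are handled", {
  cfg <- sim_config(n_patients = 50, n_genes = 1, seed = 3)
  expr <- simulate_expression(cfg, simulate_cohort(cfg))
  expect_identical(dim(expr), c(1L, 50L))
})

test_that("reference profiles are permutations with planted reversers at the extremes", {
  universe <- sprintf("g%03d", 1:200)
  up <- universe[1:10]; down <- universe[11:20]
  refs <- simulate_reference_profiles(universe, up, down,
                                      n_drugs = 6, n_reversers = 2, seed = 4)
  expect_identical(nrow(refs), 6L)
  for (i in 1:6) expect_setequal(refs$ranked[[i]], universe)
  for (i in 1:2) {
    expect_equal(connectivity_score(up, down, refs$ranked[[i]])$score, -1)
  }
  expect_error(simulate_reference_profiles(universe, up, c(up[1], down),
                                           n_drugs = 2, n_reversers = 0),
               "overlap")
})
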