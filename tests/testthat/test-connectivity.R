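test_that("KS connectivity score matches the hand-enumerated 6-gene example", {
  ref <- paste0("g", 1:6)
  cs <- connectivity_score("g1", "g6", ref)
  # ks_up = max(1/1 - 1/6) = 5/6; ks_down = -max(6/6 - 0/1) = -1; raw = 11/6
  expect_equal(cs$raw, 5 / 6 + 1, tolerance = 1e-12)
  expect_equal(cs$score, 1)
  expect_equal(connectivity_score("g6", "g1", ref)$score, -1)
})

test_that("connectivity score hits the extremes and the same-sign convention", {
  universe <- sprintf("g%03d", 1:100)
  up <- universe[1:10]; down <- universe[91:100]
  expect_equal(connectivity_score(up, down, universe)$score, 1)
  expect_equal(connectivity_score(down, up, universe)$score, -1)
  # both sets at the top: the two KS statistics share a sign -> 0
  both_top <- connectivity_score(universe[1:5], universe[6:10], universe)
  expect_equal(both_top$score, 0)
  expect_error(connectivity_score(up, up, universe), "overlap")
  expect_error(connectivity_score("absent", down, universe), "absent")
})

test_that("connectivity score is antisymmetric under reversal and swap", {
  withr::local_seed(71)
  universe <- sprintf("g%03d", 1:150)
  n <- length(universe)
  # independent oracle for the one-sided KS pieces, used both to cross-check
  # the score and to detect near-ties between the two running-sum maxima
  # (reversal flips the list by 1/n, so a tie within 2/n can legitimately
  # change which maximum wins and break exact antisymmetry)
  ks_parts <- function(set, ref) {
    v <- sort(match(set, ref)); t <- length(v); j <- seq_len(t)
    c(a = max(j / t - v / n), b = max(v / n - (j - 1) / t))
  }
  stable <- function(up, down, ref) {
    all(vapply(list(up, down), function(s) {
      p <- ks_parts(s, ref); abs(p["a"] - p["b"]) > 2 / n
    }, logical(1)))
  }
  for (i in 1:30) {
    picked <- sample(universe, 24)
    up <- picked[1:12]; down <- picked[13:24]
    ref <- sample(universe)
    s <- connectivity_score(up, down, ref)$score
    # swap antisymmetry is exact
    expect_equal(connectivity_score(down, up, ref)$score, -s, tolerance = 1e-12)
    expect_true(s >= -1 && s <= 1)
    if (stable(up, down, ref) && stable(up, down, rev(ref))) {
      expect_equal(sign(connectivity_score(up, down, rev(ref))$score), -sign(s))
      expect_equal(connectivity_score(up, down, rev(ref))$score, -s,
                   tolerance = 4 / n)
    }
  }
  # unequal set sizes keep scores in [-1, 1]
  for (i in 1:10) {
    up <- sample(universe, 5); down <- sample(setdiff(universe, up), 17)
    s <- connectivity_score(up, down, sample(universe))$score
    expect_true(s >= -1 && s <= 1)
  }
})

test_that("screen recovers a planted reverser and is deterministic in the seed", {
  universe <- sprintf("g%03d", 1:300)
  up <- universe[1:15]; down <- universe[16:30]
  refs <- simulate_reference_profiles(universe, up, down,
                                      n_drugs = 21, n_reversers = 1, seed = 72)
  query <- list(up_genes = up, down_genes = down)
  out <- connectivity_screen(query, refs, n_perm = 200, seed = 73)
  rev_row <- out[out$drug == "reverser_01", ]
  expect_equal(rev_row$score, -1)
  expect_identical(which.min(out$score), which(out$drug == "reverser_01"))
  expect_lt(rev_row$fdr, 0.05)
  expect_identical(rev_row$direction, "negative_recommended")
  out2 <- connectivity_screen(query, refs, n_perm = 200, seed = 73)
  expect_identical(out$p, out2$p)
  expect_error(connectivity_screen(query, refs, n_perm = 50), "at least 100")
  expect_error(connectivity_screen(query, refs[1, ], n_perm = 200), "at least 2")
})

test_that("query signatures recover planted differential genes and truncate", {
  withr::local_seed(74)
  n_genes <- 400
  lab <- factor(rep(c("low", "high"), each = 8), levels = c("low", "high"))
  expr <- matrix(rnorm(n_genes * 16), n_genes, 16,
                 dimnames = list(sprintf("g%03d", 1:n_genes), NULL))
  up_true <- sprintf("g%03d", 1:30); down_true <- sprintf("g%03d", 31:60)
  expr[up_true, lab == "low"] <- expr[up_true, lab == "low"] + 5
  expr[down_true, lab == "low"] <- expr[down_true, lab == "low"] - 5
  de <- moderated_t(fit_gene_lfc(expr, lab))
  # at effect >> noise the planted genes are many orders of magnitude below
  # any null gene, so a stringent cutoff recovers membership exactly
  sig <- build_query_signature(de, fdr_cutoff = 1e-8)
  expect_setequal(sig$up_genes, up_true)
  expect_setequal(sig$down_genes, down_true)
  trunc <- build_query_signature(de, max_set = 10)
  expect_lte(length(trunc$up_genes), 10)
  expect_lte(length(trunc$down_genes), 10)
  # null data: no significant signature
  null_de <- moderated_t(fit_gene_lfc(matrix(rnorm(n_genes * 16), n_genes, 16), lab))
  expect_error(build_query_signature(null_de), "no significant signature")
})

test_that("IC50 comparison runs ANOVA plus starred pairwise tests vs the reference", {
  withr::local_seed(75)
  same <- tibble::tibble(
    drug = rep(c("tamoxifen", "a", "b"), each = 4),
    cell_line = rep(paste0("cl", 1:4), 3),
    ln_ic50 = rep(c(1, 2, 3, 4), 3)
  )
  res <- compare_ic50(same, "tamoxifen")
  expect_equal(res$anova$F, 0)
  expect_true(all(res$pairwise$stars == ""))

  tab <- tibble::tibble(
    drug = rep(c("tamoxifen", "potent"), each = 10),
    cell_line = rep(paste0("cl", 1:10), 2),
    ln_ic50 = c(rnorm(10, 0, 1), rnorm(10, -3, 1))
  )
  res <- compare_ic50(tab, "tamoxifen")
  expect_identical(res$pairwise$stars[res$pairwise$drug == "potent"], "***")
  expect_lt(res$pairwise$mean_diff[1], 0)
  expect_error(compare_ic50(tab, "letrozole"), "not present")
  expect_error(compare_ic50(tab[c(1, 11:20), ], "tamoxifen"), "at least 2")
})
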