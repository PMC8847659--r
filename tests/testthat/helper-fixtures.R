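# Shared fixtures: all data built in code at test time.

small_config <- function(n = 400, seed = 101, ...) {
  sim_config(n_patients = n, n_genes = 200, seed = seed, ...)
}

# A tiny hand-built cohort with only high/low patients and SKP2 CN aligned
# with the signature group (used for the rho = 1 concordance identity).
aligned_cohort <- function(n_per_arm = 5) {
  n <- 2 * n_per_arm
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    ubiq_group = factor(rep(c("high", "low"), each = n_per_arm),
                        levels = c("high", "intermediate", "low", "unclassified")),
    cn_skp2 = rep(c(0L, 1L), each = n_per_arm)
  )
}

expect_no_na <- function(x) expect_false(anyNA(x))
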