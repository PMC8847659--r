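# Bidirectional KS connectivity scoring of ranked perturbation profiles
# against an up/down query signature, a permutation screen with BH FDR, and
# the IC50 potency comparison.

#' Build an up/down query signature from differential expression
#'
#' Selects significant genes (BH-adjusted p below `fdr_cutoff`) and splits
#' them by log-fold-change sign; each set is truncated to the `max_set` genes
#' with the largest |moderated t|. "Up" genes are those higher under the
#' contrast orientation of the supplied fit.
#'
#' @param de A `ubistrat_de` object from [moderated_t()].
#' @param fdr_cutoff Adjusted-p threshold (default 0.05).
#' @param max_set Maximum genes per set (default 150).
#' @return An object of class `ubistrat_signature`: list with `up_genes`,
#'   `down_genes`, `fdr_cutoff`, `max_set`.
#' @export
build_query_signature <- function(de, fdr_cutoff = 0.05, max_set = 150L) {
  stopifnot(inherits(de, "ubistrat_de"))
  tab <- de$table
  sig <- tab[tab$p_adj < fdr_cutoff, ]
  pick <- function(rows) {
    rows <- rows[order(-abs(rows$t_mod)), ]
    head(rows$gene_id, max_set)
  }
  up <- pick(sig[sig$lfc > 0, ])
  down <- pick(sig[sig$lfc < 0, ])
  if (length(up) == 0 || length(down) == 0) {
    abort("no significant signature: empty up or down set at this FDR cutoff")
  }
  structure(list(up_genes = up, down_genes = down,
                 fdr_cutoff = fdr_cutoff, max_set = max_set),
            class = "ubistrat_signature")
}

# One-sided KS running statistic for a gene set at `positions` (1-based ranks
# in a list of length n): a = max_j(j/t - V(j)/n), b = max_j(V(j)/n - (j-1)/t);
# returns a if a > b else -b.
ks_set_stat <- function(positions, n) {
  t <- length(positions)
  v <- sort(positions)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

# Raw bidirectional score from set positions; 0 unless the two one-sided
# statistics have opposite signs.
raw_connectivity <- function(up_pos, down_pos, n) {
  ks_up <- ks_set_stat(up_pos, n)
  ks_down <- ks_set_stat(down_pos, n)
  if (sign(ks_up) == sign(ks_down)) 0 else ks_up - ks_down
}

# Extremal raw scores for set sizes (tu, td) in a list of length n: attained
# with one set flush at the top and the other flush at the bottom.
extreme_raw <- function(tu, td, n) {
  pos_max <- (1 - tu / n) + (1 - (td - 1) / n)
  neg_min <- -((1 - td / n) + (1 - (tu - 1) / n))
  c(pos_max = pos_max, neg_min = neg_min)
}

normalize_raw <- function(raw, tu, td, n) {
  ex <- extreme_raw(tu, td, n)
  ifelse(raw > 0, raw / ex[["pos_max"]],
         ifelse(raw < 0, raw / abs(ex[["neg_min"]]), 0))
}

#' Bidirectional KS connectivity score
#'
#' Measures whether a ranked reference perturbation profile matches (+) or
#' reverses (-) an up/down query signature, using the classic bidirectional
#' Kolmogorov-Smirnov enrichment statistic: one running-sum KS statistic per
#' set, combined only when the two point in opposite directions, then scaled
#' by the maximum raw score attainable with the sets at the list extremes so
#' the result lies in \[-1, 1\].
#'
#' @param up,down Disjoint gene sets (character vectors).
#' @param ranked_reference Permutation of the gene universe ordered from most
#'   up-regulated to most down-regulated under the perturbation.
#' @return List with `raw` and normalized `score`.
#' @export
#' @examples
#' connectivity_score(c("g1"), c("g6"), paste0("g", 1:6))$score  # +1
connectivity_score <- function(up, down, ranked_reference) {
  if (length(intersect(up, down)) > 0) abort("up and down sets overlap")
  if (length(up) == 0 || length(down) == 0) abort("both gene sets must be non-empty")
  if (anyDuplicated(ranked_reference)) abort("ranked reference contains duplicates")
  up_pos <- match(up, ranked_reference)
  down_pos <- match(down, ranked_reference)
  if (anyNA(up_pos) || anyNA(down_pos)) {
    abort("gene set contains genes absent from the reference universe")
  }
  n <- length(ranked_reference)
  raw <- raw_connectivity(up_pos, down_pos, n)
  list(raw = raw, score = unname(normalize_raw(raw, length(up), length(down), n)))
}

#' Permutation connectivity screen over a reference set
#'
#' Scores the query signature against every (drug, cell line) reference
#' profile, computes a two-sided permutation p-value per profile by rescoring
#' `n_perm` random same-size gene-set pairs drawn from the universe, adjusts
#' across profiles with Benjamini-Hochberg, and labels each profile:
#' `negative_recommended` (reverses the query signature at FDR below
#' `fdr_threshold`), `positive` (matches it at that FDR), or `null`.
#'
#' @param query A `ubistrat_signature` from [build_query_signature()] (or a
#'   list with `up_genes`/`down_genes`).
#' @param refs Reference profiles as returned by
#'   [simulate_reference_profiles()] (tibble with `drug`, `cell_line` and a
#'   `ranked` list-column) or read via [read_reference_profiles()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @param fdr_threshold FDR threshold for the direction label (default 0.05).
#' @return A tibble of class `ubistrat_screen` with columns `drug`,
#'   `cell_line`, `score`, `p`, `fdr`, `direction`.
#' @export
connectivity_screen <- function(query, refs, n_perm = 1000L, seed = 1L,
                                fdr_threshold = 0.05) {
  if (n_perm < 100) abort("`n_perm` must be at least 100")
  if (nrow(refs) < 2) abort("need at least 2 reference profiles")
  up <- query$up_genes
  down <- query$down_genes
  if (length(intersect(up, down)) > 0) abort("up and down sets overlap")
  withr::local_seed(seed)
  tu <- length(up); td <- length(down)
  res <- vector("list", nrow(refs))
  for (i in seq_len(nrow(refs))) {
    ranked <- refs$ranked[[i]]
    n <- length(ranked)
    obs <- connectivity_score(up, down, ranked)$score
    null_scores <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      pos <- sample.int(n, tu + td)
      null_scores[b] <- normalize_raw(
        raw_connectivity(pos[seq_len(tu)], pos[tu + seq_len(td)], n), tu, td, n)
    }
    # plain Monte-Carlo estimate (no +1 correction): a profile more extreme
    # than every permutation earns p = 0, as in classic connectivity screens
    p <- sum(abs(null_scores) >= abs(obs)) / n_perm
    res[[i]] <- tibble(drug = refs$drug[i], cell_line = refs$cell_line[i],
                       score = obs, p = p)
  }
  out <- bind_rows(res)
  out$fdr <- benjamini_hochberg(out$p)
  out$direction <- ifelse(out$fdr < fdr_threshold & out$score < 0, "negative_recommended",
                          ifelse(out$fdr < fdr_threshold & out$score > 0, "positive", "null"))
  class(out) <- c("ubistrat_screen", class(out))
  out
}

#' Compare drug potencies (log IC50) against a reference drug
#'
#' One-way ANOVA of natural-log IC50 across drugs, followed by pairwise Welch
#' t tests of every drug against the reference (e.g. the standard of care),
#' annotated with significance stars (`***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05).
#'
#' @param table Tibble/data frame with columns `drug`, `cell_line`, `ln_ic50`.
#' @param reference_drug Name of the comparator drug (must be present).
#' @return An object of class `ubistrat_ic50`: list with the `anova`
#'   (`ubistrat_anova`) and a `pairwise` tibble (`drug`, `mean_diff`, `t`,
#'   `df`, `p`, `stars`).
#' @export
compare_ic50 <- function(table, reference_drug) {
  need <- c("drug", "ln_ic50")
  if (!all(need %in% names(table))) abort("table needs `drug` and `ln_ic50` columns")
  if (!reference_drug %in% table$drug) {
    abort(sprintf("reference drug '%s' not present in the table", reference_drug))
  }
  counts <- table(table$drug)
  if (any(counts < 2)) abort("every drug needs at least 2 IC50 values")
  aov_res <- one_way_anova(table$ln_ic50, table$drug)
  ref_vals <- table$ln_ic50[table$drug == reference_drug]
  others <- setdiff(unique(table$drug), reference_drug)
  pw <- lapply(others, function(d) {
    tt <- welch_t_test(table$ln_ic50[table$drug == d], ref_vals)
    tibble(drug = d, mean_diff = tt$estimate, t = tt$t, df = tt$df,
           p = tt$p, stars = p_stars(tt$p))
  })
  structure(list(anova = aov_res, pairwise = bind_rows(pw),
                 reference_drug = reference_drug),
            class = "ubistrat_ic50")
}
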