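# End-to-end pipeline: stratify -> proxy validation -> clinical association
# -> drug repurposing, with a run manifest that reconciles row counts.

#' Pipeline run configuration
#'
#' Collects paths, mode flags, thresholds and the master seed for
#' [run_pipeline()]. When `cohort` is `NULL` a synthetic cohort (and
#' expression matrix) is generated from `sim`. All stage seeds are derived
#' deterministically from `seed`.
#'
#' @param cohort Optional path to a cohort TSV, or a cohort tibble.
#' @param expression Optional path to an expression TSV, or a matrix.
#' @param refs Optional path to a reference rank-matrix TSV, or a reference
#'   tibble; when absent the repurposing stage screens simulated profiles
#'   with planted reversers.
#' @param ic50 Optional path to an IC50 TSV, or a tibble; enables the potency
#'   comparison.
#' @param sim A [sim_config()] used when no cohort is supplied.
#' @param mode Signature mode passed to [stratify_cohort()].
#' @param three_group_survival Keep intermediate patients as a survival
#'   stratum instead of the default high-vs-low comparison.
#' @param pooled_t Use pooled-variance t tests for the pairwise p27
#'   comparison instead of Welch.
#' @param fdr_threshold,alpha Significance thresholds in (0, 1).
#' @param n_perm Permutations for the connectivity screen.
#' @param reference_drug Comparator for the IC50 stage.
#' @param stages Character vector of stages to run, in order, from
#'   `c("stratify", "proxy", "clinical", "repurpose")`.
#' @param seed Master seed.
#' @param out_dir Optional directory; when set, every result table is written
#'   there as TSV.
#' @return A list of class `ubistrat_run_config`.
#' @export
run_config <- function(cohort = NULL, expression = NULL, refs = NULL, ic50 = NULL,
                       sim = sim_config(),
                       mode = c("cn_usp10", "cn_usp13", "expression"),
                       three_group_survival = FALSE,
                       pooled_t = FALSE,
                       fdr_threshold = 0.05, alpha = 0.05,
                       n_perm = 1000L,
                       reference_drug = "tamoxifen",
                       stages = c("stratify", "proxy", "clinical", "repurpose"),
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  for (th in c(fdr_threshold = fdr_threshold, alpha = alpha)) {
    if (!is.numeric(th) || th <= 0 || th >= 1) abort("thresholds must lie in (0, 1)")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  for (p in c(cohort, expression, refs, ic50)) {
    if (is.character(p) && !file.exists(p)) {
      abort(sprintf("referenced path does not exist: %s", p))
    }
  }
  structure(list(
    cohort = cohort, expression = expression, refs = refs, ic50 = ic50,
    sim = sim, mode = mode,
    three_group_survival = three_group_survival, pooled_t = pooled_t,
    fdr_threshold = fdr_threshold, alpha = alpha,
    n_perm = as.integer(n_perm), reference_drug = reference_drug,
    stages = stages, seed = as.integer(seed), out_dir = out_dir
  ), class = "ubistrat_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat key-value YAML mirroring the arguments of [run_config()]; keys under
#' `sim:` are passed to [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A `ubistrat_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$nb_coefficients)) {
    sim_args$nb_coefficients <- unlist(sim_args$nb_coefficients)
  }
  if (!is.null(sim_args$subtype_proportions)) {
    sim_args$subtype_proportions <- unlist(sim_args$subtype_proportions)
  }
  y$sim <- NULL
  args <- c(y, list(sim = do.call(sim_config, sim_args)))
  do.call(run_config, args)
}

pipeline_stage <- function(name, expr, manifest_env) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "ubistrat_stage_error",
          partial_manifest = manifest_env$manifest)
  })
}

subtype_slices <- function(cohort) {
  c(list(all = cohort),
    split(cohort, cohort$subtype)[intersect(c("luminal", "her2", "tnbc"),
                                            unique(as.character(cohort$subtype)))])
}

#' Run the full signature pipeline
#'
#' Orchestrates the whole analysis on a real or synthetic cohort:
#' stratification by the ubiquitination signature, proxy validation (p27
#' one-way ANOVA per subtype, high-vs-low t test, moderated-t differential
#' expression and LFC concordance), clinical association (log-rank survival,
#' stage/grade chi-square, NB regression of positive-node counts per
#' subtype), and optionally the connectivity screen and IC50 comparison.
#' Identical configuration and seed give an identical bundle; every exclusion
#' (unclassified patients, skipped strata) is recorded in the manifest.
#'
#' @param config A [run_config()].
#' @return A list of class `ubistrat_report` with elements `manifest`,
#'   `cohort`, `counts`, `p27_anova`, `p27_ttest`, `de`, `concordance`,
#'   `survival`, `km_curves`, `stage_chisq`, `grade_chisq`, `nodes_nbfit`,
#'   `screen`, `ic50`, `signature`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ubistrat_run_config"))
  menv <- new.env()
  menv$manifest <- tibble(key = "seed", value = as.character(config$seed))
  note <- function(key, value) {
    menv$manifest <- bind_rows(menv$manifest,
                               tibble(key = key, value = as.character(value)))
  }
  report <- list()

  # --- inputs ---------------------------------------------------------------
  cohort <- pipeline_stage("input", {
    if (is.null(config$cohort)) {
      simulate_cohort(config$sim, seed = derive_seed(config$seed, 0))
    } else if (is.character(config$cohort)) {
      read_cohort(config$cohort)
    } else {
      as_tibble(config$cohort)
    }
  }, menv)
  note("n_patients", nrow(cohort))

  expr <- pipeline_stage("input", {
    if (!is.null(config$expression)) {
      if (is.character(config$expression)) read_expression(config$expression)
      else config$expression
    } else if (is.null(config$cohort)) {
      simulate_expression(config$sim, cohort)
    } else {
      NULL
    }
  }, menv)

  # --- stratify -------------------------------------------------------------
  if ("stratify" %in% config$stages) {
    cohort <- pipeline_stage("stratify", {
      if (config$mode == "expression" && is.null(expr)) {
        abort("expression mode requires an expression matrix")
      }
      stratify_cohort(cohort, mode = config$mode, expr = expr)
    }, menv)
    report$counts <- group_counts(cohort)
    n_uncl <- attr(cohort, "n_unclassified") %||% 0L
    note("n_unclassified", n_uncl)
    note("n_classified", nrow(cohort) - n_uncl)
  }
  report$cohort <- cohort

  slices <- subtype_slices(cohort)

  # --- proxy validation -----------------------------------------------------
  if ("proxy" %in% config$stages) {
    res <- pipeline_stage("proxy", {
      if (is.null(expr)) {
        abort("expression matrix is required for the proxy-validation stage")
      }
      anova_rows <- list(); ttest_rows <- list()
      for (nm in names(slices)) {
        sl <- slices[[nm]]
        sl <- sl[sl$ubiq_group %in% c("high", "intermediate", "low"), ]
        tab <- table(droplevels(sl$ubiq_group))
        if (length(tab) >= 2 && all(tab >= 2)) {
          av <- one_way_anova(sl$p27, droplevels(sl$ubiq_group))
          anova_rows[[nm]] <- tibble(
            subtype = nm, F = av$F, df_between = av$df_between,
            df_within = av$df_within, p = av$p,
            mean_high = av$group_means$high %||% NA_real_,
            mean_intermediate = av$group_means$intermediate %||% NA_real_,
            mean_low = av$group_means$low %||% NA_real_
          )
        }
        hi <- sl$p27[sl$ubiq_group == "high"]
        lo <- sl$p27[sl$ubiq_group == "low"]
        if (length(hi) >= 2 && length(lo) >= 2) {
          tt <- welch_t_test(hi, lo, pooled = config$pooled_t)
          ttest_rows[[nm]] <- tibble(subtype = nm, t = tt$t, df = tt$df,
                                     p = tt$p, mean_diff = tt$estimate)
        }
      }
      conc_rows <- list()
      lum <- slices[["luminal"]] %||% cohort
      lab <- ifelse(lum$ubiq_group == "low", "low",
                    ifelse(lum$ubiq_group == "high", "high", NA))
      sub_expr <- expr[, match(lum$patient_id, colnames(expr)), drop = FALSE]
      de <- moderated_t(fit_gene_lfc(sub_expr, factor(lab, levels = c("low", "high"))))
      for (nm in names(slices)) {
        cc <- tryCatch(lfc_concordance(expr, slices[[nm]]), error = function(e) NULL)
        if (!is.null(cc)) {
          conc_rows[[nm]] <- tibble(subtype = nm, rho = cc$rho, p = cc$p,
                                    n_genes = cc$n_genes)
        }
      }
      list(anova = bind_rows(anova_rows), ttest = bind_rows(ttest_rows),
           de = de, concordance = bind_rows(conc_rows))
    }, menv)
    report$p27_anova <- res$anova
    report$p27_ttest <- res$ttest
    report$de <- res$de
    report$concordance <- res$concordance
    note("proxy_subtypes", nrow(res$anova))
  }

  # --- clinical association -------------------------------------------------
  if ("clinical" %in% config$stages) {
    res <- pipeline_stage("clinical", {
      surv_rows <- list(); curve_rows <- list()
      stage_rows <- list(); grade_rows <- list(); nb_rows <- list()
      for (nm in names(slices)) {
        sl <- slices[[nm]]
        lr <- tryCatch(survival_by_group(sl, three_group = config$three_group_survival),
                       error = function(e) NULL)
        if (!is.null(lr)) {
          surv_rows[[nm]] <- tibble(subtype = nm, chi2 = lr$chi2, df = lr$df, p = lr$p)
          cv <- attr(lr, "curves")
          cv$subtype <- nm
          curve_rows[[nm]] <- cv
        }
        sl3 <- sl[sl$ubiq_group %in% c("high", "intermediate", "low"), ]
        sl3$ubiq_group <- droplevels(sl3$ubiq_group)
        for (what in c("stage", "grade")) {
          tab <- table(sl3$ubiq_group, droplevels(factor(sl3[[what]])))
          cs <- tryCatch(chi_square_independence(tab), error = function(e) NULL)
          if (!is.null(cs)) {
            row <- tibble(subtype = nm, chi2 = cs$chi2, df = cs$df, p = cs$p,
                          low_expected = cs$low_expected)
            if (what == "stage") stage_rows[[nm]] <- row else grade_rows[[nm]] <- row
          }
        }
        nb_ok <- !is.na(sl3$positive_nodes)
        if (sum(nb_ok) >= 10 && nlevels(droplevels(sl3$ubiq_group[nb_ok])) >= 2) {
          fit <- tryCatch(
            suppressWarnings(fit_negbin_glm(sl3$positive_nodes[nb_ok],
                                            sl3$ubiq_group[nb_ok])),
            error = function(e) NULL)
          if (!is.null(fit)) {
            td <- tidy(fit)
            td$subtype <- nm
            td$theta <- fit$theta
            td$converged <- fit$converged
            nb_rows[[nm]] <- td
          }
        }
      }
      list(surv = bind_rows(surv_rows), curves = bind_rows(curve_rows),
           stage = bind_rows(stage_rows), grade = bind_rows(grade_rows),
           nb = bind_rows(nb_rows))
    }, menv)
    report$survival <- res$surv
    report$km_curves <- res$curves
    report$stage_chisq <- res$stage
    report$grade_chisq <- res$grade
    report$nodes_nbfit <- res$nb
    note("clinical_subtypes", nrow(res$surv))
  }

  # --- drug repurposing -----------------------------------------------------
  if ("repurpose" %in% config$stages && !is.null(report$de)) {
    res <- pipeline_stage("repurpose", {
      sig <- build_query_signature(report$de, fdr_cutoff = config$fdr_threshold)
      refs <- if (!is.null(config$refs)) {
        if (is.character(config$refs)) read_reference_profiles(config$refs)
        else config$refs
      } else {
        simulate_reference_profiles(
          universe = report$de$table$gene_id,
          query_up = sig$up_genes, query_down = sig$down_genes,
          n_drugs = 20L, n_reversers = 2L,
          seed = derive_seed(config$seed, 2000)
        )
      }
      screen <- connectivity_screen(sig, refs, n_perm = config$n_perm,
                                    seed = derive_seed(config$seed, 3000),
                                    fdr_threshold = config$fdr_threshold)
      ic50 <- NULL
      if (!is.null(config$ic50)) {
        tab <- if (is.character(config$ic50)) read_ic50(config$ic50) else config$ic50
        ic50 <- compare_ic50(tab, config$reference_drug)
      }
      list(signature = sig, screen = screen, ic50 = ic50)
    }, menv)
    report$signature <- res$signature
    report$screen <- res$screen
    report$ic50 <- res$ic50
    note("n_recommended", sum(res$screen$direction == "negative_recommended"))
  }

  report$manifest <- menv$manifest
  class(report) <- "ubistrat_report"

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

#' Write a pipeline report bundle as TSV files
#'
#' @param report A `ubistrat_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x) > 0) {
      readr::write_tsv(as_tibble(x), file.path(out_dir, name), na = "NA",
                       progress = FALSE)
    }
  }
  w(report$manifest, "manifest.tsv")
  w(report$cohort, "cohort_stratified.tsv")
  w(report$counts, "group_counts.tsv")
  w(report$p27_anova, "anova_p27.tsv")
  w(report$p27_ttest, "ttest_p27.tsv")
  if (!is.null(report$de)) w(report$de$table, "de_signature.tsv")
  w(report$concordance, "concordance.tsv")
  w(report$survival, "survival_bygroup.tsv")
  w(report$km_curves, "km_curves.tsv")
  w(report$stage_chisq, "stage_chisq.tsv")
  w(report$grade_chisq, "grade_chisq.tsv")
  w(report$nodes_nbfit, "nodes_nbfit.tsv")
  w(report$screen, "connectivity.tsv")
  if (!is.null(report$ic50)) w(report$ic50$pairwise, "ic50_pairwise.tsv")
  invisible(report)
}
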