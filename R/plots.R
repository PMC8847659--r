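# ggplot2 visualisations for the main result types.

#' @method autoplot ubistrat_km
#' @export
autoplot.ubistrat_km <- function(object, ...) {
  df <- bind_rows(
    tibble(time = 0, survival = 1),
    as_tibble(object)[, c("time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  title = "Kaplan-Meier estimate") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by ubiquitination group
#'
#' @param cohort A stratified cohort with survival columns.
#' @param three_group Include the intermediate group.
#' @return A ggplot object.
#' @export
plot_survival_groups <- function(cohort, three_group = FALSE) {
  lr <- survival_by_group(cohort, three_group = three_group)
  curves <- attr(lr, "curves")
  start <- curves |> group_by(.data$ubiq_group) |>
    summarise(time = 0, survival = 1, .groups = "drop")
  df <- bind_rows(start, curves[, c("ubiq_group", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$ubiq_group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Overall survival",
                  colour = "Ubiquitination",
                  subtitle = sprintf("log-rank p = %.3g", lr$p)) +
    ggplot2::theme_minimal()
}

#' p27 protein level by signature group and subtype
#'
#' @param cohort A stratified cohort with a `p27` column.
#' @return A ggplot object.
#' @export
plot_p27_groups <- function(cohort) {
  df <- cohort[cohort$ubiq_group != "unclassified", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ubiq_group, y = .data$p27)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~subtype) +
    ggplot2::labs(x = "SKP2 ubiquitination group", y = "p27 (RPPA units)") +
    ggplot2::theme_minimal()
}

#' @method autoplot ubistrat_de
#' @export
autoplot.ubistrat_de <- function(object, fdr_cutoff = 0.05, ...) {
  tab <- object$table
  tab$significant <- tab$p_adj < fdr_cutoff
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$lfc, y = -log10(.data$p),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = sprintf("FDR < %.2g", fdr_cutoff)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ubistrat_nbfit
#' @export
autoplot.ubistrat_nbfit <- function(object, ...) {
  td <- tidy(object)
  td$lo <- td$estimate - 1.96 * td$std.error
  td$hi <- td$estimate + 1.96 * td$std.error
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log expected-count ratio vs high ubiquitination",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot ubistrat_screen
#' @export
autoplot.ubistrat_screen <- function(object, ...) {
  df <- as_tibble(object)
  df$drug_line <- paste(df$drug, df$cell_line, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   y = stats::reorder(.data$drug_line, .data$score),
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Normalized connectivity score", y = NULL,
                  fill = "Direction") +
    ggplot2::theme_minimal()
}

#' @method autoplot ubistrat_ic50
#' @export
autoplot.ubistrat_ic50 <- function(object, data = NULL, ...) {
  if (is.null(data)) abort("pass the IC50 table via `data` to plot distributions")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$drug, y = .data$ln_ic50)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "ln IC50") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
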