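#' Mean percent-improvement trajectories by arm
#'
#' @param summary output of [improvement_summary()].
#' @return a ggplot object.
#' @export
plot_improvement_trajectories <- function(summary) {
  need <- c("arm", "week", "mean_pi")
  if (!all(need %in% names(summary))) {
    stop_validation("summary needs arm, week and mean_pi columns")
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$week, y = .data$mean_pi,
                               colour = .data$arm, group = .data$arm)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Week", y = "Mean percent improvement",
                  colour = "Arm",
                  title = "Transcriptomic percent improvement over time") +
    ggplot2::theme_minimal()
}

#' Fraction of signature genes above improvement thresholds
#'
#' @param summary output of [improvement_summary()].
#' @return a ggplot object (one bar panel per threshold column).
#' @export
plot_improvement_thresholds <- function(summary) {
  cols <- grep("^pct_above_", names(summary), value = TRUE)
  if (!length(cols)) stop_validation("summary has no pct_above_* columns")
  long <- summary %>%
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "threshold",
                        values_to = "pct") %>%
    dplyr::mutate(threshold = paste0(">", sub("pct_above_", "", .data$threshold),
                                     "% improved"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$week), y = .data$pct,
                               fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~threshold) +
    ggplot2::labs(x = "Week", y = "Percent of signature genes", fill = "Arm",
                  title = "Signature genes crossing improvement thresholds") +
    ggplot2::theme_minimal()
}

#' Concordance of two signatures' disease effects
#'
#' Scatter of per-gene baseline lesional effects of one differential
#' expression table against a reference, over the shared genes.
#'
#' @param stats,reference outputs of [paired_lesional_de()].
#' @return a ggplot object.
#' @export
plot_signature_concordance <- function(stats, reference) {
  shared <- dplyr::inner_join(
    stats[, c("feature_id", "mean_paired_delta")],
    reference[, c("feature_id", "mean_paired_delta")],
    by = "feature_id", suffix = c("", "_ref"))
  if (!nrow(shared)) stop_insufficient("no shared features between tables")
  ggplot2::ggplot(shared,
                  ggplot2::aes(x = .data$mean_paired_delta_ref,
                               y = .data$mean_paired_delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Reference log2 LS - NL effect",
                  y = "Observed log2 LS - NL effect",
                  title = "Signature effect concordance") +
    ggplot2::theme_minimal()
}

#' Volcano plot of gene-set score contrasts
#'
#' @param diffs output of [gsva_differential()].
#' @param q_max sets with q below this are highlighted.
#' @return a ggplot object.
#' @export
plot_gsva_volcano <- function(diffs, q_max = 0.05) {
  need <- c("set_name", "delta", "q_value")
  if (!all(need %in% names(diffs))) {
    stop_validation("diffs needs set_name, delta and q_value columns")
  }
  d <- dplyr::mutate(diffs, significant = .data$q_value < q_max)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Mean LS - NL score difference",
                  y = expression(-log[10](p)),
                  colour = paste0("q < ", q_max),
                  title = "Gene-set score contrast, lesional vs nonlesional") +
    ggplot2::theme_minimal()
}

#' Serum fold changes from baseline with pointwise intervals
#'
#' @param changes output of [within_arm_change()].
#' @return a ggplot object.
#' @export
plot_serum_effects <- function(changes) {
  need <- c("analyte", "arm", "week", "estimate")
  if (!all(need %in% names(changes))) {
    stop_validation("changes needs analyte, arm, week and estimate columns")
  }
  ggplot2::ggplot(changes,
                  ggplot2::aes(x = .data$week, y = .data$estimate,
                               colour = .data$arm, group = .data$arm)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Week", y = "Mean log2 change from baseline",
                  colour = "Arm",
                  title = "Serum analyte change from baseline") +
    ggplot2::theme_minimal()
}

#' Plot residual disease expression in healed lesional skin
#'
#' Residual fold change of each signature gene against its percent
#' improvement, marking the genes called in the molecular scar.
#'
#' @param object a [molecular_scar()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scar_result <- function(object, ...) {
  d <- object$features[!object$features$unstable, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pi_in_hls,
                                  y = .data$residual_fold_change,
                                  colour = .data$in_scar)) +
    ggplot2::geom_hline(yintercept = c(-1.5, 1.5), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 75, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Percent improvement in healed lesional skin",
                  y = "Residual signed fold change vs nonlesional",
                  colour = "In scar",
                  title = paste0("Molecular scar, ", object$arm, " arm")) +
    ggplot2::theme_minimal()
}
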