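#' Plot a ROC curve
#'
#' @param object A [weighted_roc()] curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pe_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "Detection rate") +
    ggplot2::theme_minimal()
}

#' Plot a pipeline report
#'
#' Detection rate at the target FPR across the biomarker-combination
#' ladder.
#'
#' @param object A [run_pipeline()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pe_report <- function(object, ...) {
  tab <- dplyr::mutate(
    object$performance,
    combination = factor(.data$combination, levels = .data$combination)
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$combination, y = .data$dr_at_fpr)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$dr_at_fpr)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL,
                  y = sprintf("DR at %.0f%% FPR", 100 * tab$target_fpr[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot risk distributions by outcome
#'
#' @param cohort A cohort tibble with a risk column and `outcome`.
#' @param risk_col Risk column to plot.
#' @return A ggplot (log10 risk densities by outcome group).
#' @export
plot_risk_distributions <- function(cohort, risk_col = "risk") {
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = log10(.data[[risk_col]]),
                               fill = .data$outcome)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "log10 preterm-PE risk", y = "Density", fill = "Outcome") +
    ggplot2::theme_minimal()
}
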