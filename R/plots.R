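#' Plot a bootstrap ROC curve
#'
#' @param object an `lnm_roc` from [bootstrap_auc_ci()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lnm_roc <- function(object, ...) {
  df <- object$points
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step(color = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC %.2f (%.0f%% CI %.2f-%.2f)",
                                  object$auc, 100 * object$level,
                                  object$ci[1], object$ci[2])) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' @param object an `lnm_calibration` from [calibration_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lnm_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_predicted,
                                       y = .data$observed_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), color = "#2166ac") +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted probability", y = "Observed fraction",
                  size = "Nodes") +
    ggplot2::theme_minimal()
}

#' Plot a decision curve
#'
#' Net benefit of the model against the treat-all and treat-none reference
#' strategies over the threshold-probability grid.
#'
#' @param object an `lnm_decision_curve` from [decision_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lnm_decision_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("nb_model", "nb_all", "nb_none"),
                            names_to = "strategy", values_to = "net_benefit")
  df$strategy <- factor(df$strategy, c("nb_model", "nb_all", "nb_none"),
                        c("Model", "Treat all", "Treat none"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                                   color = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(-0.1, max(df$net_benefit) + 0.05)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  color = NULL) +
    ggplot2::scale_color_manual(values = c("#2166ac", "grey40", "grey70")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare model ROC curves of a pipeline run
#'
#' @param result a `pipeline_result`.
#' @param models which models to draw (default all).
#' @return a ggplot of test-cohort ROC curves.
#' @export
plot_roc_curves <- function(result, models = names(result$models)) {
  df <- purrr::imap_dfr(result$details[models], function(d, nm) {
    dplyr::mutate(d$test$roc$points, model = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity,
                                   color = .data$model)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", color = NULL) +
    ggplot2::theme_minimal()
}
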