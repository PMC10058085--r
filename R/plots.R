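#' Plot an ROC curve
#'
#' @param object a `ctp_roc` from [roc_auc()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ctp_roc <- function(object, ...) {
  co <- pROC::coords(object$roc, x = "all", transpose = FALSE)
  ggplot2::ggplot(co, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#B2182B") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot Bland-Altman agreement
#'
#' @param object a `ctp_bland_altman` from [bland_altman()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ctp_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(colour = "#B2182B", alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$lower, object$upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired FFR", y = "Difference",
                  title = sprintf("Bland-Altman: mean %.3f, limits [%.3f, %.3f]",
                                  object$mean_diff, object$lower,
                                  object$upper)) +
    ggplot2::theme_minimal()
}

#' Plot a diagnostic evaluation
#'
#' Scatter of CTP-FFR against invasive FFR with the decision thresholds,
#' the headline agreement view of the evaluation.
#'
#' @param object an `ffr_diagnostics` from [evaluate_cohort()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ffr_diagnostics <- function(object, ...) {
  thr <- object$thresholds
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$invasive_ffr, y = .data$ctp_ffr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = thr["reference"], colour = "grey50") +
    ggplot2::geom_hline(yintercept = thr["index"], colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$gray_zone), alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#2166AC",
                                            `TRUE` = "#B2182B"),
                                 name = "gray zone") +
    ggplot2::coord_equal(xlim = c(0.3, 1), ylim = c(0.3, 1)) +
    ggplot2::labs(x = "Invasive FFR", y = "CTP-FFR") +
    ggplot2::theme_minimal()
}
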