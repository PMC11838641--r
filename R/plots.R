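# Plot methods for fitted objects.

#' Propensity-score overlap plot
#'
#' Density of the cross-fitted propensity score by treatment arm; greater
#' separation reflects stronger discrimination (and less overlap).
#'
#' @param object A `ps_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ps_fit
#' @export
autoplot.ps_fit <- function(object, ...) {
  d <- tidy(object)
  d$arm <- factor(ifelse(d$A == 1, "treated", "comparator"))
  ggplot(d, aes(x = .data$ps, fill = .data$arm)) +
    geom_density(alpha = 0.4, colour = NA) +
    labs(x = "cross-fitted propensity score", y = "density",
         title = sprintf("PS overlap (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Forest plot of hazard-ratio estimates
#'
#' Point estimates and 95% confidence intervals for every (model, scheme)
#' cell of a run, with the unadjusted estimate first.
#'
#' @param object A `run_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot run_report
#' @export
autoplot.run_report <- function(object, ...) {
  d <- object$effects
  d$label <- ifelse(is.na(d$model_id), "unadjusted",
                    sprintf("model %s / %s", d$model_id, d$scheme))
  d$label <- factor(d$label, levels = rev(unique(d$label)))
  ggplot(d, aes(x = .data$hr, y = .data$label)) +
    geom_point() +
    ggplot2::geom_errorbarh(
      aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    labs(x = "hazard ratio (95% CI, log scale)", y = NULL,
         title = "Treatment-effect estimates by covariate set and weighting scheme") +
    theme_minimal()
}
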