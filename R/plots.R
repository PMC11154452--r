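# ggplot2 views of the result objects.

#' Plot a visual predictive check
#' @param object A `bu_vpc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bu_vpc
#' @export
autoplot.bu_vpc <- function(object, ...) {
  ggplot(object, aes(x = .data$t)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi,
                    group = .data$percentile), alpha = 0.25) +
    geom_line(aes(y = .data$sim_median, group = .data$percentile),
              linetype = 2) +
    geom_point(aes(y = .data$observed, shape = factor(.data$percentile))) +
    labs(x = "time (h)", y = "concentration (mg/L)",
         shape = "observed percentile",
         title = "Visual predictive check")
}

#' Plot the simulated clearance trend
#' @param object A `bu_cl_trend`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bu_cl_trend
#' @export
autoplot.bu_cl_trend <- function(object, ...) {
  ggplot(object, aes(x = .data$t)) +
    geom_ribbon(aes(ymin = .data$lo95, ymax = .data$hi95), alpha = 0.15) +
    geom_ribbon(aes(ymin = .data$lo80, ymax = .data$hi80), alpha = 0.25) +
    geom_line(aes(y = .data$mean_curve)) +
    geom_line(aes(y = .data$hlh_xlp_curve), linetype = 2) +
    labs(x = "time after first infusion (h)", y = "CL(t) / CL(0)",
         title = "Simulated population trend of clearance")
}

#' Observed versus predicted concentrations
#'
#' @param fit A `bu_fit`.
#' @param level `"individual"` (empirical Bayes) or `"population"`.
#' @return A ggplot.
#' @export
plot_obs_pred <- function(fit, level = c("individual", "population")) {
  level <- match.arg(level)
  d <- tibble(pred = predict_fit(fit, level), obs = fit$design$y)
  ggplot(d, aes(.data$pred, .data$obs)) +
    geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    labs(x = paste0("predicted (", level, ") mg/L"), y = "observed mg/L")
}

#' Residual diagnostics plot
#'
#' Conditional individual weighted residuals against time and against the
#' individual prediction.
#'
#' @param fit A `bu_fit`.
#' @return A ggplot.
#' @export
plot_icwres <- function(fit) {
  d <- icwres(fit)
  d <- tidyr::pivot_longer(d, c("t", "ipred"), names_to = "against")
  ggplot(d, aes(.data$value, .data$icwres)) +
    geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~against, scales = "free_x") +
    labs(y = "icwres")
}

#' Dose-linearity plot
#'
#' @param dl Output of [dose_linearity()].
#' @return A ggplot.
#' @export
plot_dose_linearity <- function(dl) {
  ggplot(dl, aes(.data$dose_ratio, .data$auc_dose_ratio)) +
    geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::facet_wrap(~interval) +
    labs(x = "dose ratio vs first interval",
         y = "(AUC/dose) ratio vs first interval")
}
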