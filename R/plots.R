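# ggplot2 visualizations for the fitted model, the applicability domain
# and kinetics traces.

#' Observed-versus-predicted plot for a fitted model
#'
#' @param object A `k_model`.
#' @param newdata Optional test frame plotted alongside the training rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot k_model
#' @export
autoplot.k_model <- function(object, newdata = NULL, ...) {
  obs_pred <- function(data, set) {
    tibble(abbr = data$abbr, set = set,
           observed = data[[object$response]],
           predicted = predict(object, data)$.fitted)
  }
  df <- obs_pred(object$data, "train")
  if (!is.null(newdata) && nrow(newdata)) {
    df <- bind_rows(df, obs_pred(newdata, "test"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted,
                                   colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Observed transformed K", y = "Predicted transformed K",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Williams plot of an applicability-domain report
#'
#' @param object A [williams_ad()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot williams_ad
#' @export
autoplot.williams_ad <- function(object, ...) {
  h_star <- attr(object, "h_star")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$leverage, .data$std_residual,
                               colour = .data$set)) +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = h_star, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Leverage (hat value)",
                  y = "Standardized residual", colour = NULL,
                  title = "Williams plot") +
    ggplot2::theme_minimal()
}

#' Plot kinetics traces by scavenger condition
#'
#' @param traces Tibble with `compound`, `condition`, `time_min`,
#'   `conc_mM`.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(traces) {
  ggplot2::ggplot(traces,
                  ggplot2::aes(.data$time_min, .data$conc_mM,
                               colour = .data$condition)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~compound) +
    ggplot2::labs(x = "Time (min, irradiation starts at 0)",
                  y = "Concentration (mM)", colour = "Condition") +
    ggplot2::theme_minimal()
}
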