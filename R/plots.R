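#' Plot an EVPI curve
#'
#' @param object An [evpi_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.voi_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - 2 * .data$mc_se,
                                      ymax = .data$estimate + 2 * .data$mc_se),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "EVPI (USD per person)") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A [ceac()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.voi_ceac <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability most cost-effective",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a restricted cubic spline fit over its bin means
#'
#' @param object An [fit_rcs()] object.
#' @param ... Unused.
#' @return A ggplot of bin means (points) and the fitted spline (line),
#'   with knot positions marked.
#' @exportS3Method ggplot2::autoplot
autoplot.rcs_fit <- function(object, ...) {
  grid <- seq(object$range[1], object$range[2], length.out = 400)
  df <- tibble::tibble(x = object$x, y = object$y)
  fit <- tibble::tibble(x = grid, y = predict(object, grid))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = fit, colour = "steelblue") +
    ggplot2::geom_rug(data = tibble::tibble(x = object$knots, y = NA),
                      sides = "b", colour = "firebrick",
                      inherit.aes = FALSE, ggplot2::aes(x = .data$x)) +
    ggplot2::labs(x = "focal parameter (bin means)",
                  y = "conditional term mean") +
    ggplot2::theme_minimal()
}
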