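#' Plot an exposure-response odds-ratio curve
#'
#' @param object A `cc_or_curve` from [or_curve()].
#' @param ... Unused.
#' @return A ggplot: posterior-mean OR with the 95% credible ribbon and the
#'   reference level as a dashed vertical line.
#' @method autoplot cc_or_curve
#' @export
autoplot.cc_or_curve <- function(object, ...) {
  xlab <- if (object$exposure[1] == "temp") {
    "Daily maximum temperature (°C)"
  } else {
    "3-day mean PM2.5 (µg/m³)"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = attr(object, "reference"),
                        linetype = "dashed") +
    ggplot2::labs(x = xlab, y = "Odds ratio vs reference") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cc_or_curve
#' @param curve A `cc_or_curve`.
#' @export
plot_or_curve <- function(curve, ...) autoplot(curve, ...)

#' Plot the joint odds-ratio grid
#'
#' @param object A `cc_or_grid` from [or_grid()].
#' @param ... Unused.
#' @return A ggplot tile map of posterior-mean ORs across joint exposure
#'   levels, with the reference cell marked.
#' @method autoplot cc_or_grid
#' @export
autoplot.cc_or_grid <- function(object, ...) {
  ref <- attr(object, "reference")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tmax, y = .data$pm25,
                                       fill = .data$or)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = ref[["t0"]], y = ref[["p0"]],
                      shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(trans = "log",
                                  labels = function(x) sprintf("%.2f", x)) +
    ggplot2::labs(x = "Daily maximum temperature (°C)",
                  y = "3-day mean PM2.5 (µg/m³)",
                  fill = "OR") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cc_or_grid
#' @param grid A `cc_or_grid`.
#' @export
plot_or_grid <- function(grid, ...) autoplot(grid, ...)
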