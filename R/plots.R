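#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a correlation curve
#'
#' @param object A [correlation_curve()].
#' @param ... Unused.
#' @return A ggplot with log-scaled lag axis and, when available,
#'   `G ± G_se` error bars.
#' @export
autoplot.correlation_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$G)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(G(tau))) +
    ggplot2::theme_minimal()
  if ("G_se" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$G - .data$G_se, ymax = .data$G + .data$G_se),
      linewidth = 0.3, alpha = 0.4)
  }
  p
}

#' Plot an ACF fit with residuals
#'
#' @param object An `fcs_fit`.
#' @param ... Unused.
#' @return A ggplot showing data points, the fitted model curve, and
#'   residuals in a lower facet.
#' @export
autoplot.fcs_fit <- function(object, ...) {
  r <- object$residuals
  d <- dplyr::bind_rows(
    tibble::tibble(lag = r$lag, value = r$G, what = "G(tau)", kind = "data"),
    tibble::tibble(lag = r$lag, value = r$fitted, what = "G(tau)", kind = "fit"),
    tibble::tibble(lag = r$lag, value = r$resid, what = "residual", kind = "data"))
  d$what <- factor(d$what, levels = c("G(tau)", "residual"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$kind == "data"),
                        size = 0.7, alpha = 0.6) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$kind == "fit"),
                       color = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$what), scales = "free_y") +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = NULL,
                  title = sprintf("%s fit", object$model$model_id)) +
    ggplot2::theme_minimal()
}

#' Plot a brightness regression
#'
#' @param object An `fcs_brightness`.
#' @param ... Unused.
#' @return A ggplot of mean intensity versus N with per-construct OLS lines.
#' @export
autoplot.fcs_brightness <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$N, y = .data$mean_intensity,
                               color = .data$construct)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "particle number N", y = "mean intensity (counts/s)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an intensity trace
#'
#' @param object An `intensity_trace`.
#' @param rebin Coarsening factor before plotting (default: to ~1000 bins).
#' @param ... Unused.
#' @return A ggplot of counts/s versus time.
#' @export
autoplot.intensity_trace <- function(object, rebin = NULL, ...) {
  if (is.null(rebin)) rebin <- max(1L, nrow(object) %/% 1000L)
  tr <- rebin_trace(object, rebin)
  bw <- attr(tr, "bin_width")
  ggplot2::ggplot(tibble::tibble(time = tr$time, rate = tr$counts / bw),
                  ggplot2::aes(x = .data$time, y = .data$rate)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "intensity (counts/s)") +
    ggplot2::theme_minimal()
}
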