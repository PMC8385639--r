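#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ACF fit
#'
#' @param x An `fcs_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.fcs_fit <- function(x, ...) {
  free <- x$model$free
  tibble::tibble(term = free,
                 estimate = unlist(x$params[free], use.names = FALSE),
                 std.error = unname(x$param_se[free]))
}

#' @rdname tidy.fcs_fit
#' @export
glance.fcs_fit <- function(x, ...) {
  tibble::tibble(model_id = x$model$model_id, rss = x$rss,
                 chi2_red = x$chi2_red, n_points = x$n_points,
                 n_free = x$n_free, fit_start_lag = x$fit_start_lag,
                 weighted = x$weighted, converged = x$converged,
                 g_inf_ok = x$g_inf_ok)
}

#' Tidy a model selection
#'
#' @param x An `fcs_selection`.
#' @param ... Unused.
#' @return The per-candidate table with a `chosen` flag.
#' @export
tidy.fcs_selection <- function(x, ...) {
  dplyr::mutate(x$table, chosen = .data$model_id == x$chosen)
}

#' @rdname tidy.fcs_selection
#' @export
glance.fcs_selection <- function(x, ...) {
  tibble::tibble(chosen = x$chosen, case = x$case,
                 n_candidates = nrow(x$table),
                 n_survivors = length(x$survivors), alpha = x$alpha)
}

#' Tidy a brightness regression
#'
#' @param x An `fcs_brightness`.
#' @param ... Unused.
#' @return Per-construct slopes and intercepts.
#' @export
tidy.fcs_brightness <- function(x, ...) x$fits

#' @rdname tidy.fcs_brightness
#' @export
glance.fcs_brightness <- function(x, ...) {
  if (is.null(x$contrasts)) return(tibble::tibble(n_constructs = nrow(x$fits)))
  dplyr::mutate(x$contrasts, n_constructs = nrow(x$fits))
}
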