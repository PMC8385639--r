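#' Photon and intensity trace containers
#'
#' A `photon_trace` is a tibble with one column `time` (arrival times in
#' seconds, sorted, within `[0, duration]`) and attributes `resolution`
#' (detector clock tick, s) and `duration` (s). An `intensity_trace` is a
#' tibble with columns `time` (left bin edge, s) and `counts` (non-negative
#' photon counts per bin) and attributes `bin_width` and `duration`.
#'
#' @param times Numeric vector of photon arrival times (s).
#' @param resolution Clock tick (s).
#' @param duration Total acquisition time (s); default `max(times)`.
#' @return A tibble of class `photon_trace` or `intensity_trace`.
#' @name traces
NULL

#' @rdname traces
#' @export
photon_trace <- function(times, resolution = 1e-9, duration = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times)) abort_invalid("photon timestamps must be sorted")
  if (is.null(duration)) duration <- if (length(times)) max(times) else 0
  if (length(times) && (min(times) < 0 || max(times) > duration)) {
    abort_invalid("timestamps must lie in [0, duration]")
  }
  check_pos(resolution, "resolution")
  out <- tibble::tibble(time = times)
  class(out) <- c("photon_trace", class(out))
  attr(out, "resolution") <- resolution
  attr(out, "duration") <- duration
  out
}

#' @param counts Non-negative integer photon counts per bin.
#' @param bin_width Bin width (s).
#' @rdname traces
#' @export
intensity_trace <- function(counts, bin_width) {
  check_pos(bin_width, "bin_width")
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort_invalid("counts must be non-negative")
  }
  out <- tibble::tibble(time = (seq_along(counts) - 1) * bin_width,
                        counts = counts)
  class(out) <- c("intensity_trace", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "duration") <- length(counts) * bin_width
  out
}

#' Bin photon timestamps into an intensity trace
#'
#' Bin `b` receives photons with `b*bin_width <= t < (b+1)*bin_width`
#' (half-open convention); total counts are conserved. An empty trace yields
#' a zero-count trace.
#'
#' @param trace A `photon_trace`.
#' @param bin_width Bin width (s), at least the trace resolution.
#' @return An `intensity_trace`.
#' @export
bin_timestamps <- function(trace, bin_width) {
  stopifnot(inherits(trace, "photon_trace"))
  check_pos(bin_width, "bin_width")
  if (bin_width < attr(trace, "resolution")) {
    abort_invalid("bin_width must be >= trace resolution")
  }
  duration <- attr(trace, "duration")
  n_bins <- max(1L, as.integer(ceiling(duration / bin_width - 1e-12)))
  idx <- pmin(floor(trace$time / bin_width), n_bins - 1L)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  intensity_trace(counts, bin_width)
}

#' Coarsen an intensity trace by an integer factor
#'
#' Sums each run of `factor` consecutive bins; a trailing partial run is
#' dropped. Used e.g. to rebin microsecond traces to millisecond resolution
#' before spike screening.
#'
#' @param trace An `intensity_trace`.
#' @param factor Positive integer coarsening factor.
#' @return An `intensity_trace` with `factor`-fold wider bins.
#' @export
rebin_trace <- function(trace, factor) {
  stopifnot(inherits(trace, "intensity_trace"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) abort_invalid("`factor` must be >= 1")
  if (factor == 1L) return(trace)
  n <- nrow(trace) %/% factor
  if (n < 1L) abort_invalid("trace too short for requested rebinning")
  x <- trace$counts[seq_len(n * factor)]
  counts <- colSums(matrix(x, nrow = factor))
  intensity_trace(counts, attr(trace, "bin_width") * factor)
}

trace_mean_rate <- function(trace) {
  sum(trace$counts) / attr(trace, "duration")
}
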