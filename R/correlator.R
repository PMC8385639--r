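#' Correlation curve container
#'
#' A `correlation_curve` is a tibble with columns `lag` (strictly increasing
#' lag times, s), `G` (normalized autocorrelation values; an uncorrelated
#' stationary signal gives G = 1) and optionally `G_se` (per-lag standard
#' error), with attributes `mean_intensity` (counts/s) and `duration` (s).
#'
#' @param lag Strictly increasing lag times (s).
#' @param G Correlation values.
#' @param G_se Optional per-lag standard errors (>= 0, NA allowed).
#' @param mean_intensity Mean detected intensity (counts/s).
#' @param duration Acquisition duration (s).
#' @return A tibble of class `correlation_curve`.
#' @export
correlation_curve <- function(lag, G, G_se = NULL, mean_intensity = NA_real_,
                              duration = NA_real_) {
  keep <- is.finite(lag) & is.finite(G)
  lag <- lag[keep]; G <- G[keep]
  if (!is.null(G_se)) {
    G_se <- G_se[keep]
    if (any(G_se < 0, na.rm = TRUE)) abort_invalid("G_se must be >= 0")
  }
  if (length(lag) == 0) abort_invalid("correlation curve has no finite points")
  if (any(diff(lag) <= 0)) abort_invalid("lags must be strictly increasing")
  out <- tibble::tibble(lag = lag, G = G)
  if (!is.null(G_se)) out$G_se <- G_se
  class(out) <- c("correlation_curve", class(out))
  attr(out, "mean_intensity") <- mean_intensity
  attr(out, "duration") <- duration
  out
}

# symmetrically normalized direct-sum estimator at integer bin lags:
# G(k) = mean(x_i * x_{i+k}) / (mean head * mean tail)
direct_g <- function(x, k_bins) {
  n <- length(x)
  vapply(k_bins, function(k) {
    m <- n - k
    if (m < 1L) return(NA_real_)
    head <- x[seq_len(m)]
    tail <- x[seq_len(m) + k]
    denom <- mean(head) * mean(tail)
    if (denom <= 0) return(NA_real_)
    mean(head * tail) / denom
  }, numeric(1))
}

multitau_grid <- function(n_bins, bin_width, m) {
  # lag grid in (bin units, coarsening level); level 0: 1..m at base
  # resolution, level b: (m/2+1)..m at resolution 2^b
  stopifnot(m %% 2 == 0)
  lags <- list(tibble::tibble(level = 0L, k = seq_len(m)))
  level <- 1L
  n <- n_bins %/% 2L
  while (n >= 2L * m) {
    lags[[level + 1L]] <- tibble::tibble(level = level,
                                         k = (m %/% 2L + 1L):m)
    level <- level + 1L
    n <- n %/% 2L
  }
  dplyr::bind_rows(lags)
}

#' Multi-tau autocorrelation of an intensity trace
#'
#' Emulates a hardware-style multi-tau correlator: `m` linearly spaced lag
#' channels at the base resolution, then `m/2` channels per block with the
#' trace coarsened two-fold between blocks, giving a quasi-logarithmic lag
#' grid spanning from one bin width up to a sizeable fraction of the
#' acquisition. Normalization is symmetric (product of head and tail means
#' at each lag), which suppresses slow-drift/bleaching bias and makes an
#' uncorrelated stationary signal converge to G = 1.
#'
#' Per-lag standard errors are estimated by splitting the trace into
#' `n_segments` equal segments, correlating each, and taking the standard
#' error of the segment values across segments at each shared lag.
#'
#' @param trace An `intensity_trace` with nonzero mean.
#' @param m Channels per block (even; default 16).
#' @param n_segments Segments for the uncertainty estimate (default 5;
#'   `0` disables `G_se`).
#' @return A `correlation_curve`.
#' @export
autocorrelate <- function(trace, m = 16L, n_segments = 5L) {
  stopifnot(inherits(trace, "intensity_trace"))
  x <- trace$counts
  bw <- attr(trace, "bin_width")
  if (length(x) < 2L * m) abort_invalid("trace too short for multi-tau grid")
  if (mean(x) <= 0) {
    rlang::abort("zero-mean trace: normalization undefined",
                 class = "fcspipe_undefined_normalization")
  }
  grid <- multitau_grid(length(x), bw, m)
  # lags beyond a tenth of the acquisition have too few independent
  # samples for a stable estimate; drop them
  grid <- grid[grid$k * bw * 2^grid$level <= attr(trace, "duration") / 10, ]
  main <- multitau_eval(x, bw, grid, m)
  G_se <- NULL
  if (n_segments >= 2L) {
    seg_len <- length(x) %/% n_segments
    if (seg_len >= 2L * m) {
      seg_vals <- vapply(seq_len(n_segments), function(s) {
        xs <- x[((s - 1L) * seg_len + 1L):(s * seg_len)]
        if (mean(xs) <= 0) return(rep(NA_real_, nrow(grid)))
        # evaluate on the full grid; lags beyond segment coverage give NA
        multitau_eval(xs, bw, grid, m)$G
      }, numeric(nrow(grid)))
      n_ok <- rowSums(!is.na(seg_vals))
      G_se <- apply(seg_vals, 1L, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1L))
      G_se[n_ok < 2L] <- NA_real_
    }
  }
  correlation_curve(main$lag, main$G, G_se,
                    mean_intensity = trace_mean_rate(trace),
                    duration = attr(trace, "duration"))
}

multitau_eval <- function(x, bw, grid, m) {
  max_level <- max(grid$level)
  out_G <- rep(NA_real_, nrow(grid))
  out_lag <- grid$k * bw * 2^grid$level
  xc <- x
  for (lev in 0:max_level) {
    rows <- which(grid$level == lev)
    if (length(rows)) {
      ks <- grid$k[rows]
      if (length(xc) > max(ks)) out_G[rows] <- direct_g(xc, ks)
    }
    if (lev < max_level) {
      n2 <- length(xc) %/% 2L
      if (n2 < 1L) break
      # pairwise coarsening: average adjacent bins
      xc <- (xc[seq(1L, 2L * n2, by = 2L)] + xc[seq(2L, 2L * n2, by = 2L)]) / 2
    }
  }
  tibble::tibble(lag = out_lag, G = out_G)
}

#' Brute-force autocorrelation (direct summation)
#'
#' Exact O(N*L) direct-sum estimator on a linear lag grid with the same
#' symmetric normalization as [autocorrelate()]. Intended as a slow,
#' transparent reference for validating the multi-tau estimator.
#'
#' @param trace An `intensity_trace`.
#' @param max_lag_bins Largest lag, in bins (`< nrow(trace)`).
#' @return A `correlation_curve` with lags at every bin multiple.
#' @export
correlate_direct <- function(trace, max_lag_bins) {
  stopifnot(inherits(trace, "intensity_trace"))
  x <- trace$counts
  if (max_lag_bins >= length(x)) abort_invalid("max_lag_bins must be < number of bins")
  if (mean(x) <= 0) {
    rlang::abort("zero-mean trace: normalization undefined",
                 class = "fcspipe_undefined_normalization")
  }
  k <- seq_len(max_lag_bins)
  correlation_curve(k * attr(trace, "bin_width"), direct_g(x, k),
                    mean_intensity = trace_mean_rate(trace),
                    duration = attr(trace, "duration"))
}

#' Flag intensity spikes indicative of bright aggregates
#'
#' Bins exceeding `median + k * robust SD` (robust SD from the median
#' absolute deviation, with a Poisson floor of `sqrt(median)` when the MAD
#' degenerates to zero) are flagged and merged into contiguous intervals.
#' Spikes in FCS intensity traces indicate large bright particles crossing
#' the observation volume; flagged measurements are excluded from cohort
#' statistics but retained with a QC label.
#'
#' @param trace An `intensity_trace` with at least 100 bins.
#' @param k Threshold in robust standard deviations above the median.
#' @return A tibble of flagged intervals (`start_time`, `end_time`,
#'   `n_bins`, `peak_counts`) with attributes `aggregate_suspected`
#'   (logical) and `threshold` (counts).
#' @export
detect_spikes <- function(trace, k = 5) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (nrow(trace) < 100L) abort_invalid("spike screening needs >= 100 bins")
  x <- trace$counts
  med <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) s <- sqrt(max(med, 0))
  thr <- med + k * s
  hot <- which(x > thr & s > 0)
  bw <- attr(trace, "bin_width")
  if (length(hot)) {
    run <- cumsum(c(1L, diff(hot) > 1L))
    iv <- tibble::tibble(hot = hot, run = run) |>
      dplyr::group_by(.data$run) |>
      dplyr::summarise(start_time = (min(.data$hot) - 1L) * bw,
                       end_time = max(.data$hot) * bw,
                       n_bins = dplyr::n(),
                       peak_counts = max(x[.data$hot]),
                       .groups = "drop") |>
      dplyr::select(-dplyr::any_of("run"))
  } else {
    iv <- tibble::tibble(start_time = numeric(), end_time = numeric(),
                         n_bins = integer(), peak_counts = numeric())
  }
  attr(iv, "aggregate_suspected") <- nrow(iv) > 0L
  attr(iv, "threshold") <- thr
  iv
}
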