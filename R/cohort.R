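#' Group summaries of derived quantities
#'
#' Aggregates QC-passing, converged measurements into per-group mean, SD
#' and SEM of each derived quantity. Text values in the field are usually
#' reported as mean ± SEM, while figure error bars show the SD; both are
#' returned, clearly labeled.
#'
#' @param records Fit table from [fit_records()] (or any tibble with the
#'   quantity columns).
#' @param by Character vector of grouping columns (e.g.
#'   `c("construct", "compartment")`).
#' @param quantities Quantity columns to summarize.
#' @param qc_only Keep only rows with `qc_pass` (when the column exists).
#' @return A tibble with one row per group x quantity: `n`, `mean`, `sd`,
#'   `sem` (`sem = sd/sqrt(n)`, with `n` counting non-missing values).
#' @export
summarize_groups <- function(records, by = c("construct", "compartment"),
                             quantities = c("D1", "D2", "F2", "cpm"),
                             qc_only = TRUE) {
  if (qc_only && "qc_pass" %in% names(records)) {
    records <- records[records$qc_pass %in% TRUE, ]
  }
  quantities <- intersect(quantities, names(records))
  if (!length(quantities)) abort_invalid("no quantity columns found")
  long <- records |>
    dplyr::select(dplyr::all_of(c(by, quantities))) |>
    tidyr::pivot_longer(dplyr::all_of(quantities), names_to = "quantity",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  empty <- records |>
    dplyr::distinct(dplyr::across(dplyr::all_of(by))) |>
    dplyr::anti_join(long |> dplyr::distinct(dplyr::across(dplyr::all_of(by))),
                     by = by)
  if (nrow(empty)) {
    rlang::warn(sprintf("%d group(s) had no usable values and were omitted",
                        nrow(empty)))
  }
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "quantity")))) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     .groups = "drop") |>
    dplyr::mutate(sem = .data$sd / sqrt(.data$n))
}

#' Unpaired two-sample Student's t-test
#'
#' Classical pooled-variance two-sided Student's t-test. Degenerate input
#' with zero pooled variance returns `p = 1` when the means are equal (no
#' evidence of a difference) and `p = 0` otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
ttest_unpaired <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort_invalid("each group needs at least 2 values")
  }
  df <- length(a) + length(b) - 2
  res <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(res)) {
    # constant data: zero pooled variance
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(statistic = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                parameter = df, p.value = if (eq) 1 else 0)
  }
  tibble::tibble(t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b))
}

p_stars <- function(p) {
  dplyr::case_when(p < 1e-4 ~ "****", p < 1e-3 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "n.s.")
}

#' Brightness regression: mean intensity versus particle number
#'
#' For each construct, fits an ordinary least-squares line of the mean
#' detected intensity on the fitted particle number N across measurements.
#' The slope is the apparent molecular brightness (counts/s per particle):
#' oligomeric particles carry more fluorophores and give a steeper line.
#' Pairwise slope contrasts between constructs are reported with a z-test
#' on the slope difference.
#'
#' @param points Tibble with columns `construct`, `N`, `mean_intensity`
#'   (one row per measurement, e.g. a [fit_records()] table).
#' @return Object of class `fcs_brightness`: `$fits` (per-construct slope,
#'   SE, intercept, n) and `$contrasts` (pairwise slope ratios and z-tests).
#' @export
brightness_regression <- function(points) {
  stopifnot(all(c("construct", "N", "mean_intensity") %in% names(points)))
  points <- points[is.finite(points$N) & is.finite(points$mean_intensity), ]
  fits <- points |>
    dplyr::group_by(.data$construct) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) abort_invalid("need >= 3 points per construct")
      if (stats::sd(d$N) == 0) {
        abort_invalid("degenerate N spread: regression undefined")
      }
      m <- stats::lm(mean_intensity ~ N, data = d)
      cf <- summary(m)$coefficients
      tibble::tibble(slope = cf["N", "Estimate"],
                     slope_se = cf["N", "Std. Error"],
                     intercept = cf["(Intercept)", "Estimate"],
                     n = nrow(d))
    }) |>
    dplyr::ungroup()
  cons <- fits$construct
  contrasts <- NULL
  if (length(cons) >= 2) {
    pairs <- utils::combn(seq_along(cons), 2)
    contrasts <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      dz <- (fits$slope[i1] - fits$slope[i2]) /
        sqrt(fits$slope_se[i1]^2 + fits$slope_se[i2]^2)
      tibble::tibble(construct_a = cons[i1], construct_b = cons[i2],
                     slope_ratio = fits$slope[i1] / fits$slope[i2],
                     z = dz, p = 2 * stats::pnorm(-abs(dz)))
    })
  }
  structure(list(fits = fits, contrasts = contrasts,
                 points = tibble::as_tibble(points)),
            class = "fcs_brightness")
}

#' @export
print.fcs_brightness <- function(x, ...) {
  cat("brightness regression (mean intensity ~ N):\n")
  print(x$fits)
  if (!is.null(x$contrasts)) {
    cat("slope contrasts:\n")
    print(dplyr::mutate(x$contrasts, sig = p_stars(.data$p)))
  }
  invisible(x)
}

#' Condition report across constructs and compartments
#'
#' Reproduces the comparison structure of a multi-construct FCS cohort:
#' per construct x compartment the fraction of measurements classified as
#' one-component ("Case 1") versus two-component ("Case 2") diffusion,
#' group summaries of the derived quantities, and pairwise Student's
#' t-tests between constructs within each compartment. Raw p-values are
#' reported with the usual star conventions (no multiplicity correction).
#'
#' @param records Fit table from [fit_records()].
#' @param by Grouping columns; first element is the contrast key.
#' @param test_quantities Quantities to t-test pairwise across constructs.
#' @return Object of class `fcs_condition_report` with tibbles
#'   `$case_fractions`, `$summaries`, `$tests`.
#' @export
compare_conditions <- function(records, by = c("construct", "compartment"),
                               test_quantities = c("D1", "D2", "F2", "cpm")) {
  usable <- records[records$converged %in% TRUE, ]
  case_fractions <- usable |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n = dplyr::n(),
                     n_case1 = sum(.data$case %in% "Case 1"),
                     n_case2 = sum(.data$case %in% "Case 2"),
                     .groups = "drop") |>
    dplyr::mutate(frac_case1 = .data$n_case1 / .data$n,
                  frac_case2 = .data$n_case2 / .data$n)
  summaries <- summarize_groups(records, by = by,
                                quantities = test_quantities)
  key <- by[1]
  strata <- setdiff(by, key)
  tests <- NULL
  qc <- if ("qc_pass" %in% names(records)) records[records$qc_pass %in% TRUE, ]
        else usable
  if (length(unique(qc[[key]])) >= 2) {
    split_keys <- if (length(strata)) {
      dplyr::distinct(qc, dplyr::across(dplyr::all_of(strata)))
    } else tibble::tibble(.dummy = 1)
    tests <- purrr::map_dfr(seq_len(nrow(split_keys)), function(i) {
      d <- qc
      for (s in strata) d <- d[d[[s]] == split_keys[[s]][i], ]
      groups <- unique(d[[key]])
      if (length(groups) < 2) return(NULL)
      pairs <- utils::combn(groups, 2)
      purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
        purrr::map_dfr(intersect(test_quantities, names(d)), function(q) {
          va <- d[[q]][d[[key]] == pairs[1, j]]
          vb <- d[[q]][d[[key]] == pairs[2, j]]
          va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
          if (length(va) < 2 || length(vb) < 2) return(NULL)
          res <- ttest_unpaired(va, vb)
          out <- tibble::tibble(group_a = pairs[1, j], group_b = pairs[2, j],
                                quantity = q)
          for (s in strata) out[[s]] <- split_keys[[s]][i]
          dplyr::bind_cols(out, res)
        })
      })
    })
    if (!is.null(tests) && nrow(tests)) {
      tests <- dplyr::mutate(tests, sig = p_stars(.data$p))
    }
  }
  structure(list(case_fractions = case_fractions, summaries = summaries,
                 tests = tests, by = by),
            class = "fcs_condition_report")
}

#' @export
print.fcs_condition_report <- function(x, ...) {
  cat("== case classification ==\n"); print(x$case_fractions)
  cat("== group summaries (mean, SD, SEM) ==\n"); print(x$summaries)
  if (!is.null(x$tests) && nrow(x$tests)) {
    cat("== pairwise Student's t-tests ==\n"); print(x$tests)
  } else {
    cat("== pairwise tests: fewer than two groups ==\n")
  }
  invisible(x)
}
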