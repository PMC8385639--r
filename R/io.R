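#' Read and write trace files
#'
#' Plain-text layouts with `#`-prefixed header lines followed by one column
#' of data. Timestamp layout: `# type: timestamps`, `# resolution_s:`,
#' `# duration_s:`, column `time_s`. Binned layout: `# type: binned`,
#' `# bin_width_s:`, column `counts`. All numbers are written with 17
#' significant digits so a write/read round trip is exact.
#'
#' @param path File path.
#' @param trace A `photon_trace` or `intensity_trace`.
#' @return `read_trace()` returns a `photon_trace` or `intensity_trace`;
#'   `write_trace()` returns `path` invisibly.
#' @export
read_trace <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- parse_header(lines, path)
  type <- hdr$fields[["type"]]
  if (is.null(type) || !type %in% c("timestamps", "binned")) {
    parse_error(path, 1, "missing or unknown `# type:` header")
  }
  body <- lines[-seq_len(hdr$n_header)]
  if (length(body) == 0) parse_error(path, hdr$n_header, "missing column header line")
  col <- trimws(body[1])
  data_lines <- body[-1]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  vals <- suppressWarnings(as.numeric(data_lines))
  bad <- which(is.na(vals))
  if (length(bad)) {
    parse_error(path, hdr$n_header + 1 + bad[1],
                sprintf("not a number: '%s'", data_lines[bad[1]]))
  }
  if (type == "timestamps") {
    if (col != "time_s") parse_error(path, hdr$n_header + 1, "expected column `time_s`")
    res <- header_num(hdr, "resolution_s", path)
    dur <- header_num(hdr, "duration_s", path)
    if (length(vals) > 1 && any(diff(vals) < 0)) {
      i <- which(diff(vals) < 0)[1] + 1
      parse_error(path, hdr$n_header + 1 + i, "decreasing timestamp")
    }
    photon_trace(vals, resolution = res, duration = dur)
  } else {
    if (col != "counts") parse_error(path, hdr$n_header + 1, "expected column `counts`")
    bw <- header_num(hdr, "bin_width_s", path)
    neg <- which(vals < 0)
    if (length(neg)) {
      parse_error(path, hdr$n_header + 1 + neg[1], "negative count")
    }
    intensity_trace(vals, bin_width = bw)
  }
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "photon_trace")) {
    lines <- c("# fcspipe_trace v1",
               "# type: timestamps",
               sprintf("# resolution_s: %.17g", attr(trace, "resolution")),
               sprintf("# duration_s: %.17g", attr(trace, "duration")),
               "time_s",
               sprintf("%.17g", trace$time))
  } else if (inherits(trace, "intensity_trace")) {
    lines <- c("# fcspipe_trace v1",
               "# type: binned",
               sprintf("# bin_width_s: %.17g", attr(trace, "bin_width")),
               "counts",
               sprintf("%.17g", trace$counts))
  } else {
    abort_invalid("not a trace object")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

parse_header <- function(lines, path) {
  n <- 0L
  fields <- list()
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    n <- n + 1L
    m <- stringr::str_match(ln, "^#\\s*([A-Za-z_0-9]+):\\s*(.*)$")
    if (!is.na(m[1, 2])) fields[[m[1, 2]]] <- trimws(m[1, 3])
  }
  list(n_header = n, fields = fields)
}

header_num <- function(hdr, key, path) {
  v <- hdr$fields[[key]]
  if (is.null(v)) parse_error(path, 1, sprintf("missing `# %s:` header", key))
  if (identical(v, "NA")) return(NA_real_)
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) parse_error(path, 1, sprintf("malformed `# %s:` header", key))
  x
}

parse_error <- function(path, line, msg) {
  rlang::abort(sprintf("%s:%d: %s", path, line, msg),
               class = "fcspipe_parse_error")
}

#' Read and write correlation-curve files
#'
#' Tab-separated text with `#` headers carrying the acquisition duration
#' and mean intensity, then columns `lag_s`, `G` and optionally `G_se`.
#' Full 17-significant-digit precision; the round trip is exact.
#'
#' @param path File path.
#' @param curve A [correlation_curve()].
#' @export
read_curve <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- parse_header(lines, path)
  body <- lines[-seq_len(hdr$n_header)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) parse_error(path, hdr$n_header, "no data")
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(cols[1:2], c("lag_s", "G"))) {
    parse_error(path, hdr$n_header + 1, "expected columns lag_s, G[, G_se]")
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  num <- function(i) suppressWarnings(as.numeric(vapply(rows, `[`, "", i)))
  lag <- num(1); g <- num(2)
  bad <- which(is.na(lag) | is.na(g))
  if (length(bad)) parse_error(path, hdr$n_header + 1 + bad[1], "malformed row")
  if (any(diff(lag) <= 0)) {
    i <- which(diff(lag) <= 0)[1] + 1
    parse_error(path, hdr$n_header + 1 + i, "non-increasing lag")
  }
  se <- if (length(cols) >= 3 && cols[3] == "G_se") num(3) else NULL
  correlation_curve(lag, g, se,
                    mean_intensity = if (!is.null(hdr$fields$mean_intensity_cps))
                      header_num(hdr, "mean_intensity_cps", path) else NA_real_,
                    duration = if (!is.null(hdr$fields$duration_s))
                      header_num(hdr, "duration_s", path) else NA_real_)
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  has_se <- "G_se" %in% names(curve)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  header <- c("# fcspipe_curve v1",
              sprintf("# duration_s: %.17g", attr(curve, "duration")),
              sprintf("# mean_intensity_cps: %.17g", attr(curve, "mean_intensity")))
  cols <- if (has_se) "lag_s\tG\tG_se" else "lag_s\tG"
  rows <- if (has_se) {
    paste(fmt(curve$lag), fmt(curve$G), fmt(curve$G_se), sep = "\t")
  } else {
    paste(fmt(curve$lag), fmt(curve$G), sep = "\t")
  }
  readr::write_lines(c(header, cols, rows), path)
  invisible(path)
}

run_config_fields <- c("w0", "z0", "calibration_curve", "D_ref", "candidates",
                       "alpha", "fit_start_lags", "bin_width", "m",
                       "n_segments", "spike_k", "group_by", "seed",
                       "out_dir", "regimes", "n_per_regime", "duration")

#' Validated pipeline run configuration
#'
#' Collects every tunable of the pipeline into one validated list. Unknown
#' fields are rejected. Either an observation volume (`w0`, `z0`) or a
#' calibration curve path plus `D_ref` must be supplied.
#'
#' @param ... Configuration fields: `w0`, `z0`, `calibration_curve`,
#'   `D_ref`, `candidates` (model ids), `alpha`, `bin_width`, `m`,
#'   `n_segments`, `spike_k`, `group_by`, `seed`, `out_dir`, `regimes`,
#'   `n_per_regime`, `duration`.
#' @param file Optional YAML file to read fields from (explicit arguments
#'   override file values).
#' @return A list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list()
  if (!is.null(file)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      rlang::abort("the yaml package is required to read config files")
    }
    cfg <- yaml::read_yaml(file)
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  unknown <- setdiff(names(cfg), run_config_fields)
  if (length(unknown)) {
    rlang::abort(paste0("unknown config fields: ",
                        paste(unknown, collapse = ", ")),
                 class = "fcspipe_config_error")
  }
  defaults <- list(D_ref = 400, candidates = c("D1P", "D2P"), alpha = 0.05,
                   bin_width = 1e-5, m = 16L, n_segments = 5L, spike_k = 5,
                   group_by = c("construct", "compartment"), seed = 1L,
                   regimes = c("monomer", "two_component"), n_per_regime = 3L,
                   duration = 30)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$w0) && is.null(cfg$calibration_curve)) {
    rlang::abort("config needs either w0 (and optionally z0) or a calibration_curve",
                 class = "fcspipe_config_error")
  }
  bad <- setdiff(cfg$candidates, MODEL_IDS)
  if (length(bad)) {
    rlang::abort(paste0("unknown candidate models: ", paste(bad, collapse = ", ")),
                 class = "fcspipe_config_error")
  }
  structure(cfg, class = "run_config")
}

#' Run the full simulate-correlate-fit-analyze pipeline
#'
#' Executes every stage on simulated regimes: builds the measurement
#' catalog, resolves the observation volume (direct values or dye
#' calibration), correlates and fits every trace with model selection and
#' QC, aggregates the cohort report, and (when `out_dir` is set) writes the
#' fit table, group summaries, pairwise tests and a log with the config
#' echo and session versions. Identical config and seed give identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `catalog`, `fits` (fit table), `report`
#'   (condition report), `vol`, and `paths` of any files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  vol <- if (!is.null(config$calibration_curve)) {
    calibrate_volume(read_curve(config$calibration_curve),
                     D_ref = config$D_ref)
  } else {
    observation_volume(w0 = config$w0,
                       z0 = if (is.null(config$z0)) 5 * config$w0 else config$z0)
  }
  catalog <- make_regime_catalog(seed = config$seed, regimes = config$regimes,
                                 n_per_regime = config$n_per_regime,
                                 duration = config$duration, vol = vol)
  fits <- fit_records(catalog, vol = vol,
                      candidates = as.list(config$candidates),
                      alpha = config$alpha, spike_k = config$spike_k,
                      m = config$m, n_segments = config$n_segments)
  report <- compare_conditions(fits, by = config$group_by)
  paths <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- function(name) file.path(config$out_dir, name)
    readr::write_tsv(drop_list_cols(fits), f("fit_table.tsv"))
    readr::write_tsv(report$summaries, f("group_summaries.tsv"))
    if (!is.null(report$tests)) readr::write_tsv(report$tests, f("pairwise_tests.tsv"))
    readr::write_tsv(report$case_fractions, f("case_fractions.tsv"))
    log_lines <- c(
      sprintf("fcspipe %s | R %s", as.character(utils::packageVersion("fcspipe")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("run at %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      "config:",
      vapply(names(unclass(config)), function(nm)
        sprintf("  %s: %s", nm, paste(format(config[[nm]]), collapse = ", ")),
        character(1)))
    readr::write_lines(log_lines, f("run_log.txt"))
    paths <- vapply(c("fit_table.tsv", "group_summaries.tsv",
                      "case_fractions.tsv", "run_log.txt"), f, character(1))
  }
  invisible(list(catalog = catalog, fits = fits, report = report, vol = vol,
                 paths = paths))
}

drop_list_cols <- function(df) {
  df[!vapply(df, is.list, logical(1))]
}
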