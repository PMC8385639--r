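#' Specify a simulated fluorescent species
#'
#' One row per species: diffusion coefficient, molecular brightness
#' (detected counts per second per molecule at the focus center), expected
#' molecule count in the simulation box and optional two-state blinking.
#' A telegraph blinking process with stationary dark fraction `f` and
#' relaxation time `tau` multiplies the ACF by `1 + (f/(1-f)) exp(-tau/t)`,
#' so the fitted photophysics parameter satisfies
#' `F_trip/(1+F_trip) = f/(1-f)`, i.e. `F_trip = f/(1-2f)` for `f < 1/2`.
#'
#' @param D Diffusion coefficient (um^2/s), `>= 0`.
#' @param brightness Counts/s per molecule at the focus center (>= 0).
#' @param mean_count Expected number of molecules in the simulation box.
#' @param triplet_fraction Stationary dark fraction in `[0, 1)`; 0 disables
#'   blinking.
#' @param triplet_tau Blinking relaxation time (s); required when
#'   `triplet_fraction > 0`.
#' @param label Free-text species label.
#' @return A one-row tibble; bind rows to build a mixture.
#' @export
species_spec <- function(D, brightness, mean_count, triplet_fraction = 0,
                         triplet_tau = NA_real_, label = "species") {
  check_nonneg(D, "D"); check_nonneg(brightness, "brightness")
  check_nonneg(mean_count, "mean_count")
  if (triplet_fraction < 0 || triplet_fraction >= 1) {
    abort_invalid("`triplet_fraction` must be in [0, 1)")
  }
  if (triplet_fraction > 0) check_pos(triplet_tau, "triplet_tau")
  tibble::tibble(D = D, brightness = brightness, mean_count = mean_count,
                 triplet_fraction = triplet_fraction,
                 triplet_tau = triplet_tau, label = label)
}

#' Simulation configuration
#'
#' Defines the periodic simulation box, integration/binning step, duration,
#' calibrated observation volume, uniform background and optional directed
#' flow along x. The box half-lengths must be at least `3 * (w0, w0, z0)` so
#' periodic images contribute negligibly to the detected signal.
#'
#' @param vol An [observation_volume()].
#' @param box Half-lengths (um) of the periodic cuboid; default
#'   `8 * c(w0, w0, z0)`. The hard floor is `3 * c(w0, w0, z0)`; the larger
#'   default keeps the finite-box truncation of slow relaxation modes from
#'   distorting the ACF shape (fitted diffusion times are biased by -8% at
#'   the 3x floor, -2% at 5x and about -0.5% at the default).
#' @param dt Integration step = photon bin width (s). Must satisfy
#'   `dt <= w0^2 / (20 * max D)` and, for blinking species,
#'   `dt <= triplet_tau / 5` (checked in [simulate_trace()]).
#' @param duration Acquisition length (s); default 30, matching typical
#'   in vivo confocal FCS acquisitions of 30–60 s.
#' @param background_rate Uniform background (counts/s).
#' @param flow_velocity Drift velocity along x (um/s).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(vol = observation_volume(), box = NULL, dt = 1e-5,
                       duration = 30, background_rate = 500,
                       flow_velocity = 0, seed = NULL) {
  stopifnot(inherits(vol, "observation_volume"))
  if (is.null(box)) box <- 8 * c(vol$w0, vol$w0, vol$z0)
  if (length(box) != 3 || any(box < 3 * c(vol$w0, vol$w0, vol$z0) - 1e-12)) {
    rlang::abort("box half-lengths must be >= 3 * (w0, w0, z0)",
                 class = "fcspipe_config_error")
  }
  check_pos(dt, "dt"); check_pos(duration, "duration")
  check_nonneg(background_rate, "background_rate")
  structure(list(vol = vol, box = box, dt = dt, duration = duration,
                 background_rate = background_rate,
                 flow_velocity = flow_velocity, seed = seed),
            class = "sim_config")
}

box_volume <- function(cfg) prod(2 * cfg$box)

#' Expected detected intensity and particle number of a simulation
#'
#' The mean detected rate is
#' `background + sum(mean_count * brightness) * V_det / V_box` with
#' `V_det = (pi/2)^(3/2) w0^2 z0`, and the apparent FCS particle number is
#' `concentration * V_eff` with `V_eff = pi^(3/2) w0^2 z0`.
#'
#' @param species Species tibble from [species_spec()].
#' @param cfg A [sim_config()].
#' @return A list with `mean_intensity` (counts/s) and `N` (dimensionless).
#' @export
expected_signal <- function(species, cfg) {
  v_det <- (pi / 2)^1.5 * cfg$vol$w0^2 * cfg$vol$z0
  v_box <- box_volume(cfg)
  list(mean_intensity = cfg$background_rate +
         sum(species$mean_count * species$brightness *
               (1 - species$triplet_fraction)) * v_det / v_box,
       N = sum(species$mean_count) * cfg$vol$V_eff / v_box)
}

#' Simulate a photon-count trace by Brownian dynamics
#'
#' Molecules take Brownian steps (per-axis SD `sqrt(2 D dt)`) plus uniform
#' drift in a periodic box, emit photons at a rate given by the 3D Gaussian
#' detection profile of the observation volume, optionally blink via
#' telegraph kinetics, and detected counts per bin are Poisson distributed
#' with the summed rate plus background. Fully reproducible from the seed.
#'
#' @param species Species tibble ([species_spec()] rows).
#' @param cfg A [sim_config()].
#' @param init_at_origin Start every molecule at the focus center (used for
#'   degenerate pinned-molecule checks).
#' @return An [intensity_trace()] at `dt` resolution with a `ground_truth`
#'   attribute carrying `species` and `cfg`.
#' @export
simulate_trace <- function(species, cfg, init_at_origin = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if ((is.null(species) || nrow(species) == 0) && cfg$background_rate <= 0) {
    rlang::abort("need at least one species or positive background",
                 class = "fcspipe_config_error")
  }
  if (is.null(species)) species <- species_spec(0, 0, 0)[0, ]
  d_max <- suppressWarnings(max(species$D, 0))
  if (d_max > 0 && cfg$dt > cfg$vol$w0^2 / (20 * d_max) + 1e-15) {
    rlang::abort(sprintf(
      "dt = %g too coarse for fastest species: need dt <= w0^2/(20 D) = %g",
      cfg$dt, cfg$vol$w0^2 / (20 * d_max)), class = "fcspipe_config_error")
  }
  blink <- species$triplet_fraction > 0
  if (any(blink) && cfg$dt > min(species$triplet_tau[blink]) / 5 + 1e-15) {
    rlang::abort("dt must be <= triplet_tau/5 for blinking species",
                 class = "fcspipe_config_error")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_steps <- as.integer(round(cfg$duration / cfg$dt))
  counts <- bd_simulate_counts(
    n_steps, cfg$dt,
    species$D, species$brightness, as.integer(round(species$mean_count)),
    species$triplet_fraction,
    ifelse(is.na(species$triplet_tau), 0, species$triplet_tau),
    cfg$flow_velocity,
    cfg$box[1], cfg$box[2], cfg$box[3],
    cfg$vol$w0, cfg$vol$z0, cfg$background_rate,
    init_at_origin)
  out <- intensity_trace(counts, cfg$dt)
  attr(out, "ground_truth") <- list(species = species, cfg = cfg)
  out
}

#' Synthesize a correlation curve directly from a model
#'
#' Evaluates a closed-form ACF model on a lag grid and adds independent
#' Gaussian perturbations — a fast fixture generator for fitting tests.
#' With `noise_sd = 0` the exact model curve is returned.
#'
#' @param model An [acf_model()] or model id.
#' @param params Parameter list ([acf_params()] or named list).
#' @param lags Lag grid (s); default quasi-log grid 1e-5 to 1 s.
#' @param noise_sd Per-lag noise SD, scalar or vector.
#' @param seed Optional integer seed.
#' @return A [correlation_curve()] with `G_se = noise_sd` when noisy.
#' @export
synthesize_acf <- function(model, params, lags = NULL, noise_sd = 0,
                           seed = NULL) {
  if (is.null(lags)) lags <- 10^seq(-5, 0, length.out = 120)
  g <- acf_eval(model, lags, params)
  if (!is.null(seed)) set.seed(seed)
  se <- NULL
  if (any(noise_sd > 0)) {
    noise_sd <- rep_len(noise_sd, length(lags))
    g <- g + stats::rnorm(length(lags), 0, noise_sd)
    se <- noise_sd
  }
  correlation_curve(lags, g, se)
}

#' Quasi-logarithmic lag grid
#'
#' Log-spaced lag times matching the span of the multi-tau correlator;
#' convenient for [synthesize_acf()] fixtures.
#'
#' @param lag_min,lag_max Grid limits (s).
#' @param n Number of lags.
#' @return Numeric vector of lag times (s).
#' @export
default_lag_grid <- function(lag_min = 1e-5, lag_max = 1, n = 120) {
  10^seq(log10(lag_min), log10(lag_max), length.out = n)
}

#' Catalog of simulated measurement regimes
#'
#' Generates labeled fixture measurements with known ground truth covering
#' the regimes of an in vivo FCS study of a tagged oligomerizing protein in
#' motor neurons:
#' \describe{
#'   \item{monomer}{single species at ~30 um^2/s (free fluorescent protein),}
#'   \item{two_component}{fast monomer (19 um^2/s) plus slow complex
#'     (0.9 um^2/s) with slow amplitude fraction drawn in \[0.2, 0.6\],}
#'   \item{truncated}{single fast species (oligomerization-deficient
#'     truncation),}
#'   \item{truncated_weak}{fast species plus a weak intermediate component
#'     (diffusion-time ratio drawn in 5–20, amplitude 0.2),}
#'   \item{flow}{bright slow particles in directed flow at 54.5 um/s
#'     (blood-flow positive control),}
#'   \item{aggregate}{monomer background plus rare very bright slow
#'     aggregates producing intensity spikes.}
#' }
#'
#' @param seed Integer seed; each record gets a deterministic sub-seed.
#' @param regimes Subset of regime names to generate.
#' @param n_per_regime Records per regime.
#' @param duration Trace length (s) per record.
#' @param vol Observation volume.
#' @param brightness Monomer brightness (counts/s/molecule); default 8000,
#'   typical of a well-excited fluorescent protein (3-10 kHz/molecule).
#' @return A tibble with one row per measurement: ids, `construct`,
#'   `compartment`, list-columns `species` and `cfg`, ground-truth columns
#'   (`D1_true`, `D2_true`, `F2_true`, `v_true`) and a `trace` list-column.
#' @export
make_regime_catalog <- function(seed = 1,
                                regimes = c("monomer", "two_component",
                                            "truncated", "truncated_weak",
                                            "flow", "aggregate"),
                                n_per_regime = 1, duration = 30,
                                vol = observation_volume(),
                                brightness = 5000) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  set.seed(seed)
  n_for <- function(target_n, cfg) target_n * box_volume(cfg) / vol$V_eff
  base_cfg <- function(seed_i, flow = 0) {
    sim_config(vol = vol, duration = duration, flow_velocity = flow,
               seed = seed_i)
  }
  rows <- list()
  i <- 0L
  for (rg in regimes) {
    for (rep_i in seq_len(n_per_regime)) {
      i <- i + 1L
      seed_i <- (seed * 10000L + i) %% .Machine$integer.max
      cfg <- base_cfg(seed_i, flow = if (rg == "flow") 54.5 else 0)
      n_box <- n_for(1, cfg)
      rec <- switch(rg,
        monomer = list(
          species = species_spec(30, brightness, n_box, label = "FP"),
          construct = "FP", D1 = 30, D2 = NA, F2 = NA, v = NA),
        two_component = {
          f2 <- stats::runif(1, 0.2, 0.6)
          list(species = dplyr::bind_rows(
                 species_spec(19, brightness, n_box * (1 - f2), label = "FP-Smn monomer"),
                 species_spec(0.9, brightness, n_box * f2, label = "FP-Smn complex")),
               construct = "FP-Smn", D1 = 19, D2 = 0.9, F2 = f2, v = NA)
        },
        truncated = list(
          species = species_spec(25, brightness, n_box, label = "FP-SmnDex6,7"),
          construct = "FP-SmnDex6,7", D1 = 25, D2 = NA, F2 = NA, v = NA),
        truncated_weak = {
          ratio <- stats::runif(1, 5, 20)
          list(species = dplyr::bind_rows(
                 species_spec(25, brightness, n_box * 0.8, label = "fast"),
                 species_spec(25 / ratio, brightness, n_box * 0.2, label = "intermediate")),
               construct = "FP-SmnDex6,7", D1 = 25, D2 = 25 / ratio,
               F2 = 0.2, v = NA)
        },
        flow = {
          cfg_f <- base_cfg(seed_i, flow = 54.5)
          list(species = species_spec(2, 4 * brightness, n_for(1, cfg_f),
                                      label = "blood cell"),
               construct = "blood", D1 = 2, D2 = NA, F2 = NA, v = 54.5)
        },
        aggregate = list(
          species = dplyr::bind_rows(
            species_spec(30, brightness, n_box, label = "FP"),
            species_spec(0.5, 50 * brightness, 10, label = "aggregate")),
          construct = "FP-aggregate", D1 = 30, D2 = 0.5, F2 = NA, v = NA)
      )
      trace <- simulate_trace(rec$species, cfg)
      rows[[i]] <- tibble::tibble(
        measurement_id = sprintf("%s_%02d", rg, rep_i),
        regime = rg, construct = rec$construct,
        compartment = if (rg == "flow") "blood" else "cytoplasm",
        fish = sprintf("fish%02d", rep_i), cell = "cell1",
        spot = sprintf("spot%02d", i),
        D1_true = rec$D1, D2_true = rec$D2, F2_true = rec$F2,
        v_true = rec$v,
        species = list(rec$species), cfg = list(cfg), trace = list(trace))
    }
  }
  dplyr::bind_rows(rows)
}
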