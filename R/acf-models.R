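#' Closed-form FCS autocorrelation models
#'
#' Model functions for the normalized autocorrelation function (ACF) G(tau) of
#' confocal FCS measurements: one- and two-component free 3D diffusion through
#' a 3D Gaussian observation volume, with an optional photophysical (triplet)
#' relaxation prefactor, and a diffusion-plus-flow model for directed
#' transport. All models share the parameterization
#' \itemize{
#'   \item `N` — mean number of particles in the observation volume,
#'   \item `F_trip`, `tau_trip` — photophysical fraction parameter and
#'     relaxation time (s); the prefactor is
#'     `1 + (F_trip/(1+F_trip)) * exp(-tau/tau_trip)`,
#'   \item `tau_D1`, `tau_D2` — diffusion times (s) of the fast and slow
#'     components (convention: `tau_D1 <= tau_D2`),
#'   \item `F2` — amplitude fraction of the slow component, in \[0, 1\],
#'   \item `tau_f` — flow lag time (s), with flow velocity `v = w0/tau_f`,
#'   \item `K` — structure factor z0/w0 of the observation volume,
#'   \item `G_inf` — long-lag convergence value, approximately 1 for the
#'     normalization used throughout this package.
#' }
#'
#' The single-component diffusive factor is
#' `(1 + tau/tau_D)^-1 * (1 + tau/(K^2 tau_D))^-1/2`; the two-component model
#' is the amplitude-weighted sum with weights `1-F2` and `F2`; the
#' diffusion-plus-flow model multiplies the diffusive factor by
#' `exp(-(tau/tau_f)^2 / (1 + tau/tau_D1))`. The pure-flow model
#' (`acf_flow()`) is the `tau_D1 -> Inf` limit, `(1/N) exp(-(tau/tau_f)^2)`.
#'
#' Note the photophysical prefactor uses `F_trip/(1+F_trip)`, not the also
#' common `F/(1-F)` form; with this parameterization the stationary dark
#' fraction of a two-state blinking fluorophore is `F_trip/(1+F_trip)`.
#'
#' @param tau Lag time(s) in seconds, `>= 0`. Vectorized.
#' @param N Mean particle number in the observation volume (> 0).
#' @param tau_D1,tau_D2 Diffusion times in seconds (> 0).
#' @param F2 Amplitude fraction of component 2 in \[0, 1\].
#' @param F_trip Photophysical fraction parameter (>= 0).
#' @param tau_trip Photophysical relaxation time in seconds (> 0).
#' @param tau_f Flow lag time in seconds (> 0).
#' @param K Structure factor z0/w0 (> 1).
#' @param G_inf Long-lag convergence value.
#' @return Numeric vector of G(tau) values, same length as `tau`.
#' @examples
#' acf_d1p(0, N = 5, tau_D1 = 1e-3)                  # 1/5 + 1 = 1.2
#' acf_d1p(1e-3, N = 2, tau_D1 = 1e-3, K = 5, G_inf = 0)
#' @name acf_models
NULL

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "fcspipe_invalid_parameter")
}

check_pos <- function(x, name) {
  if (is.null(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort_invalid(sprintf("`%s` must be finite and > 0", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (is.null(x) || any(is.na(x)) || any(x < 0)) {
    abort_invalid(sprintf("`%s` must be >= 0", name))
  }
  invisible(x)
}

# single-species diffusive decay factor of a 3D Gaussian volume
diff_factor <- function(tau, tau_D, K) {
  1 / (1 + tau / tau_D) / sqrt(1 + tau / (K^2 * tau_D))
}

triplet_prefactor <- function(tau, F_trip, tau_trip) {
  1 + (F_trip / (1 + F_trip)) * exp(-tau / tau_trip)
}

#' @rdname acf_models
#' @export
acf_d1p <- function(tau, N, tau_D1, K = 5, G_inf = 1) {
  check_nonneg(tau, "tau")
  check_pos(N, "N"); check_pos(tau_D1, "tau_D1"); check_pos(K, "K")
  (1 / N) * diff_factor(tau, tau_D1, K) + G_inf
}

#' @rdname acf_models
#' @export
acf_d1p_triplet <- function(tau, N, F_trip, tau_trip, tau_D1, K = 5, G_inf = 1) {
  check_nonneg(tau, "tau")
  check_pos(N, "N"); check_pos(tau_D1, "tau_D1"); check_pos(K, "K")
  check_nonneg(F_trip, "F_trip"); check_pos(tau_trip, "tau_trip")
  (1 / N) * triplet_prefactor(tau, F_trip, tau_trip) *
    diff_factor(tau, tau_D1, K) + G_inf
}

#' @rdname acf_models
#' @export
acf_d2p <- function(tau, N, tau_D1, tau_D2, F2, K = 5, G_inf = 1,
                    F_trip = 0, tau_trip = NULL) {
  check_nonneg(tau, "tau")
  check_pos(N, "N"); check_pos(tau_D1, "tau_D1"); check_pos(tau_D2, "tau_D2")
  check_pos(K, "K"); check_nonneg(F_trip, "F_trip")
  if (is.na(F2) || F2 < 0 || F2 > 1) abort_invalid("`F2` must be in [0, 1]")
  pre <- if (F_trip > 0) {
    check_pos(tau_trip, "tau_trip")
    triplet_prefactor(tau, F_trip, tau_trip)
  } else 1
  (1 / N) * pre * ((1 - F2) * diff_factor(tau, tau_D1, K) +
                     F2 * diff_factor(tau, tau_D2, K)) + G_inf
}

#' @rdname acf_models
#' @export
acf_flow_diffusion <- function(tau, N, tau_D1, tau_f, K = 5, G_inf = 1) {
  check_nonneg(tau, "tau")
  check_pos(N, "N"); check_pos(tau_D1, "tau_D1"); check_pos(tau_f, "tau_f")
  check_pos(K, "K")
  (1 / N) * diff_factor(tau, tau_D1, K) *
    exp(-(tau / tau_f)^2 / (1 + tau / tau_D1)) + G_inf
}

#' @rdname acf_models
#' @export
acf_flow <- function(tau, N, tau_f, G_inf = 1) {
  check_nonneg(tau, "tau")
  check_pos(N, "N"); check_pos(tau_f, "tau_f")
  (1 / N) * exp(-(tau / tau_f)^2) + G_inf
}

# ---------------------------------------------------------------------------
# Model registry and parameter container

MODEL_IDS <- c("D1P", "D1P_TRIP", "D2P", "D2P_TRIP", "D1P_FLOW", "FLOW")

model_registry <- list(
  D1P      = list(params = c("N", "tau_D1", "K", "G_inf"),
                  free = c("N", "tau_D1", "G_inf"), fit_start = 1e-5),
  D1P_TRIP = list(params = c("N", "F_trip", "tau_trip", "tau_D1", "K", "G_inf"),
                  free = c("N", "F_trip", "tau_trip", "tau_D1", "G_inf"),
                  fit_start = 1e-6),
  D2P      = list(params = c("N", "tau_D1", "tau_D2", "F2", "K", "G_inf"),
                  free = c("N", "tau_D1", "tau_D2", "F2", "G_inf"),
                  fit_start = 1e-5),
  D2P_TRIP = list(params = c("N", "F_trip", "tau_trip", "tau_D1", "tau_D2",
                             "F2", "K", "G_inf"),
                  free = c("N", "F_trip", "tau_trip", "tau_D1", "tau_D2",
                           "F2", "G_inf"),
                  fit_start = 1e-6),
  D1P_FLOW = list(params = c("N", "tau_D1", "tau_f", "K", "G_inf"),
                  free = c("N", "tau_D1", "tau_f", "G_inf"), fit_start = 1e-5),
  FLOW     = list(params = c("N", "tau_f", "G_inf"),
                  free = c("N", "tau_f", "G_inf"), fit_start = 1e-5)
)

# models nested within each candidate (simpler ⊂ richer), used by F-tests
nesting_map <- list(
  D1P_TRIP = "D1P",
  D2P      = "D1P",
  D2P_TRIP = c("D2P", "D1P_TRIP", "D1P"),
  D1P_FLOW = c("D1P", "FLOW")
)

#' Construct a validated ACF parameter set
#'
#' Bundles the full symbol set of the ACF models into a named list with
#' invariant checks: `N > 0`, times `> 0`, `0 <= F2 <= 1`, `K > 1`,
#' `tau_trip < tau_D1` and `tau_D1 <= tau_D2` when both members are present.
#' Optional symbols are left `NA` when a model does not use them.
#'
#' @inheritParams acf_models
#' @return A list of class `acf_params`.
#' @export
acf_params <- function(N, tau_D1 = NA, tau_D2 = NA, F2 = NA,
                       F_trip = NA, tau_trip = NA, tau_f = NA,
                       K = 5, G_inf = 1) {
  check_pos(N, "N")
  check_pos(K, "K")
  if (K <= 1) abort_invalid("`K` must be > 1 (elongated observation volume)")
  if (!is.na(tau_D1)) check_pos(tau_D1, "tau_D1")
  if (!is.na(tau_D2)) {
    check_pos(tau_D2, "tau_D2")
    if (!is.na(tau_D1) && tau_D1 > tau_D2) {
      abort_invalid("ordering convention requires tau_D1 <= tau_D2")
    }
  }
  if (!is.na(F2) && (F2 < 0 || F2 > 1)) abort_invalid("`F2` must be in [0, 1]")
  if (!is.na(F_trip)) check_nonneg(F_trip, "F_trip")
  if (!is.na(tau_trip)) {
    check_pos(tau_trip, "tau_trip")
    if (!is.na(tau_D1) && tau_trip >= tau_D1) {
      abort_invalid("tau_trip must be < tau_D1 (photophysics faster than diffusion)")
    }
  }
  if (!is.na(tau_f)) check_pos(tau_f, "tau_f")
  structure(list(N = N, F_trip = F_trip, tau_trip = tau_trip,
                 tau_D1 = tau_D1, tau_D2 = tau_D2, F2 = F2, tau_f = tau_f,
                 K = K, G_inf = G_inf),
            class = "acf_params")
}

#' Specify which ACF model to evaluate or fit
#'
#' An `acf_model` names one of the closed-form models and partitions its
#' symbols into free (fitted) and fixed parameters. The default free set
#' fits everything except the structure factor `K`, which is fixed to its
#' calibrated value.
#'
#' @param model_id One of `"D1P"`, `"D1P_TRIP"`, `"D2P"`, `"D2P_TRIP"`,
#'   `"D1P_FLOW"`, `"FLOW"`.
#' @param free Character vector of free parameter names; default per model.
#' @param fixed Named list of fixed parameter values (e.g. `list(K = 5)`).
#' @return A list of class `acf_model` with fields `model_id`, `free`,
#'   `fixed`, `fit_start`.
#' @export
acf_model <- function(model_id, free = NULL, fixed = list()) {
  model_id <- match.arg(model_id, MODEL_IDS)
  reg <- model_registry[[model_id]]
  if (is.null(free)) free <- setdiff(reg$free, names(fixed))
  bad <- setdiff(free, reg$params)
  if (length(bad)) abort_invalid(paste0("free parameters not in model: ",
                                        paste(bad, collapse = ", ")))
  if (length(intersect(free, names(fixed)))) {
    abort_invalid("free and fixed parameter sets overlap")
  }
  covered <- union(free, names(fixed))
  defaults <- list(K = 5, G_inf = 1)
  missing <- setdiff(reg$params, union(covered, names(defaults)))
  if (length(missing)) {
    abort_invalid(paste0("model symbols neither free nor fixed: ",
                         paste(missing, collapse = ", ")))
  }
  for (nm in setdiff(names(defaults), covered)) fixed[[nm]] <- defaults[[nm]]
  structure(list(model_id = model_id, free = free, fixed = fixed,
                 fit_start = reg$fit_start),
            class = "acf_model")
}

#' Evaluate an ACF model from a parameter list
#'
#' @param model An `acf_model` or a model id string.
#' @param tau Lag times (s).
#' @param params An `acf_params` object or named list holding every symbol
#'   the model needs.
#' @return Numeric vector of G(tau).
#' @export
acf_eval <- function(model, tau, params) {
  id <- if (inherits(model, "acf_model")) model$model_id else
    match.arg(model, MODEL_IDS)
  p <- params
  switch(id,
    D1P = acf_d1p(tau, p$N, p$tau_D1, p$K, p$G_inf),
    D1P_TRIP = acf_d1p_triplet(tau, p$N, p$F_trip, p$tau_trip, p$tau_D1,
                               p$K, p$G_inf),
    D2P = acf_d2p(tau, p$N, p$tau_D1, p$tau_D2, p$F2, p$K, p$G_inf),
    D2P_TRIP = acf_d2p(tau, p$N, p$tau_D1, p$tau_D2, p$F2, p$K, p$G_inf,
                       F_trip = p$F_trip, tau_trip = p$tau_trip),
    D1P_FLOW = acf_flow_diffusion(tau, p$N, p$tau_D1, p$tau_f, p$K, p$G_inf),
    FLOW = acf_flow(tau, p$N, p$tau_f, p$G_inf)
  )
}

# ---------------------------------------------------------------------------
# Observation volume and unit conversions

#' Calibrated confocal observation volume
#'
#' @param w0 Radial 1/e^2 radius (micrometers).
#' @param z0 Axial 1/e^2 distance (micrometers); default `K * w0`.
#' @param K Structure factor z0/w0; ignored when `z0` is given.
#' @return A list of class `observation_volume` with fields `w0`, `z0`, `K`
#'   and the effective volume `V_eff = pi^(3/2) w0^2 z0` (micrometers^3).
#' @export
observation_volume <- function(w0 = 0.25, z0 = NULL, K = 5) {
  check_pos(w0, "w0")
  if (is.null(z0)) {
    check_pos(K, "K")
    z0 <- K * w0
  }
  check_pos(z0, "z0")
  structure(list(w0 = w0, z0 = z0, K = z0 / w0,
                 V_eff = pi^1.5 * w0^2 * z0),
            class = "observation_volume")
}

#' @export
print.observation_volume <- function(x, ...) {
  cat(sprintf("observation volume: w0 = %.4g um, z0 = %.4g um, K = %.4g, V_eff = %.4g um^3\n",
              x$w0, x$z0, x$K, x$V_eff))
  invisible(x)
}

#' Convert between diffusion time and diffusion coefficient
#'
#' The diffusion time of a species through a Gaussian observation volume of
#' radial waist `w0` is `tau_D = w0^2 / (4 D)`.
#'
#' @param tau_D Diffusion time (s).
#' @param D Diffusion coefficient (um^2/s).
#' @param vol An `observation_volume`, or a numeric `w0` in micrometers.
#' @return `tau_to_diffusion()` gives D in um^2/s; `diffusion_to_tau()` gives
#'   tau_D in seconds.
#' @export
tau_to_diffusion <- function(tau_D, vol = observation_volume()) {
  w0 <- if (inherits(vol, "observation_volume")) vol$w0 else vol
  check_pos(tau_D, "tau_D"); check_pos(w0, "w0")
  w0^2 / (4 * tau_D)
}

#' @rdname tau_to_diffusion
#' @export
diffusion_to_tau <- function(D, vol = observation_volume()) {
  w0 <- if (inherits(vol, "observation_volume")) vol$w0 else vol
  check_pos(D, "D"); check_pos(w0, "w0")
  w0^2 / (4 * D)
}

#' Root-mean-square displacement of a freely diffusing particle
#'
#' Uses the one-dimensional convention `sqrt(2 D t)`.
#'
#' @param D Diffusion coefficient (um^2/s), `>= 0`.
#' @param t Time (s), `>= 0`.
#' @return Displacement in micrometers.
#' @export
rms_displacement <- function(D, t) {
  check_nonneg(D, "D"); check_nonneg(t, "t")
  sqrt(2 * D * t)
}
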