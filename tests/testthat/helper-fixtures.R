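# Lazily built, cached simulation fixtures shared across test files.
# Building them once keeps the heavy Brownian-dynamics work bounded.

.fx <- new.env(parent = emptyenv())

# ten 30-s single-species acquisitions at D = 30 um^2/s, N ~ 1 (the
# free-fluorescent-protein regime), each correlated and fitted with both
# the plain and the triplet one-component model
single_species_fits <- function() {
  if (!is.null(.fx$single)) return(.fx$single)
  vol <- observation_volume()
  .fx$single <- lapply(1:10, function(s) {
    cfg <- sim_config(vol = vol, duration = 30, seed = s)
    sp <- species_spec(30, 8000, prod(2 * cfg$box) / vol$V_eff, label = "FP")
    tr <- simulate_trace(sp, cfg)
    cv <- autocorrelate(tr)
    list(seed = s, vol = vol, cfg = cfg, curve = cv,
         fit_trip = suppressWarnings(fit_acf(cv, acf_model("D1P_TRIP"))),
         fit_d1p = suppressWarnings(fit_acf(cv, acf_model("D1P"))))
  })
  .fx$single
}

# exact hand-evaluated one-component model value used as an arithmetic oracle
d1p_by_hand <- function(tau, N, tau_D, K, G_inf) {
  (1 / N) * (1 / (1 + tau / tau_D)) * (1 + tau / (K^2 * tau_D))^(-0.5) + G_inf
}

random_valid_params <- function() {
  tau_trip <- 10^stats::runif(1, -6, -4.5)
  tau_D1 <- 10^stats::runif(1, -4, -2.5)
  list(N = 10^stats::runif(1, -0.5, 1.5),
       F_trip = stats::runif(1, 0, 1),
       tau_trip = tau_trip,
       tau_D1 = tau_D1,
       tau_D2 = tau_D1 * 10^stats::runif(1, 0.5, 2.5),
       F2 = stats::runif(1),
       tau_f = 10^stats::runif(1, -3, -2),
       K = stats::runif(1, 3, 8),
       G_inf = 1)
}
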