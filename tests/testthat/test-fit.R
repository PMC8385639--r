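test_that("noise-free curves are recovered to machine-level accuracy", {
  truth <- list(N = 2.5, tau_D1 = 4e-4, tau_D2 = 2e-2, F2 = 0.35, K = 5,
                G_inf = 1)
  cv <- synthesize_acf("D2P", truth, default_lag_grid())
  fit <- fit_acf(cv, acf_model("D2P"), init = truth)
  expect_true(fit$converged)
  for (nm in c("N", "tau_D1", "tau_D2", "F2", "G_inf")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-6)
  }
  # the optimum is reached from perturbed starts as well
  set.seed(51)
  for (i in 1:10) {
    init <- truth
    for (nm in c("N", "tau_D1", "tau_D2", "F2")) {
      init[[nm]] <- truth[[nm]] * stats::runif(1, 0.5, 2)
    }
    init$F2 <- min(init$F2, 1)
    f2 <- fit_acf(cv, acf_model("D2P"), init = init)
    expect_equal(f2$params$tau_D1, truth$tau_D1, tolerance = 1e-4)
    expect_equal(f2$params$tau_D2, truth$tau_D2, tolerance = 1e-4)
  }
})

test_that("data-driven initialization lands near the truth and is deterministic", {
  cv <- synthesize_acf("D1P", list(N = 3, tau_D1 = 1e-3, K = 5, G_inf = 1),
                       default_lag_grid())
  init <- default_init(cv, acf_model("D1P"))
  expect_lt(abs(log2(init$tau_D1 / 1e-3)), 1)  # within a factor 2
  expect_lt(abs(init$N / 3 - 1), 0.35)
  expect_identical(init, default_init(cv, acf_model("D1P")))
  # a flat curve is unfittable
  flat <- correlation_curve(default_lag_grid(), rep(1, 120))
  expect_error(default_init(flat, acf_model("D1P")),
               class = "fcspipe_flat_curve")
})

test_that("degenerate fit inputs raise errors rather than silent success", {
  cv <- synthesize_acf("D1P", list(N = 2, tau_D1 = 1e-3, K = 5, G_inf = 1),
                       10^seq(-5, 0, length.out = 4))
  expect_error(fit_acf(cv, acf_model("D2P")),
               class = "fcspipe_invalid_parameter")
})

test_that("a drifting long-lag plateau triggers the convergence warning", {
  cv <- synthesize_acf("D1P", list(N = 2, tau_D1 = 1e-3, K = 5, G_inf = 1.08),
                       default_lag_grid())
  expect_warning(fit_acf(cv, acf_model("D1P")),
                 class = "fcspipe_g_inf_warning")
})

test_that("two-component parameters are recovered under realistic noise", {
  truth <- list(N = 1, tau_D1 = 3e-4, tau_D2 = 3e-2, F2 = 0.4, K = 5,
                G_inf = 1)
  errs <- sapply(1:10, function(s) {
    cv <- synthesize_acf("D2P", truth, default_lag_grid(), noise_sd = 0.005,
                         seed = 60 + s)
    fit <- suppressWarnings(fit_acf(cv, acf_model("D2P")))
    c(t1 = abs(fit$params$tau_D1 / truth$tau_D1 - 1),
      t2 = abs(fit$params$tau_D2 / truth$tau_D2 - 1),
      f2 = abs(fit$params$F2 - truth$F2))
  })
  expect_lt(stats::median(errs["t1", ]), 0.2)
  expect_lt(stats::median(errs["t2", ]), 0.2)
  expect_lt(stats::median(errs["f2", ]), 0.15)
})

test_that("fits respect the component ordering convention", {
  truth <- list(N = 1, tau_D1 = 3e-4, tau_D2 = 1e-2, F2 = 0.7, K = 5,
                G_inf = 1)
  cv <- synthesize_acf("D2P", truth, default_lag_grid(), noise_sd = 0.003,
                       seed = 4)
  # start with the labels swapped; the fit must come back ordered
  init <- list(N = 1, tau_D1 = 1e-2, tau_D2 = 3e-4, F2 = 0.3, K = 5,
               G_inf = 1)
  init$tau_D2 <- 5e-2  # keep within bounds but misordered relative to truth
  fit <- suppressWarnings(fit_acf(cv, acf_model("D2P")))
  expect_lte(fit$params$tau_D1, fit$params$tau_D2)
})

test_that("the F-test keeps the simple model under the null at the nominal rate", {
  truth <- list(N = 1.5, tau_D1 = 5e-4, K = 5, G_inf = 1)
  picks <- sapply(1:50, function(s) {
    cv <- synthesize_acf("D1P", truth, default_lag_grid(), noise_sd = 0.004,
                         seed = 100 + s)
    sel <- suppressWarnings(select_model(cv, list("D1P", "D2P")))
    sel$chosen
  })
  expect_lte(sum(picks == "D2P"), 2 * 0.05 * 50)
})

test_that("a clearly two-component truth is identified nearly always", {
  truth <- list(N = 1, tau_D1 = 5e-4, tau_D2 = 1e-2, F2 = 0.4, K = 5,
                G_inf = 1)
  picks <- sapply(1:20, function(s) {
    cv <- synthesize_acf("D2P", truth, default_lag_grid(), noise_sd = 0.004,
                         seed = 200 + s)
    sel <- suppressWarnings(select_model(cv, list("D1P", "D2P")))
    sel$chosen
  })
  expect_gte(mean(picks == "D2P"), 0.9)
})

test_that("volume calibration inverts the diffusion-time relation", {
  # exact curve: tau_D = 39.0625 us with D_ref = 400 gives w0 = 0.25 um
  cv <- synthesize_acf("D1P", list(N = 1, tau_D1 = 39.0625e-6, K = 5,
                                   G_inf = 1),
                       10^seq(-6.5, -1, length.out = 100))
  vol <- calibrate_volume(cv, D_ref = 400)
  expect_equal(vol$w0, 0.25, tolerance = 1e-4)
  expect_equal(vol$K, 5, tolerance = 1e-3)
  vol2 <- calibrate_volume(cv, D_ref = 800)
  expect_equal(vol2$w0, 0.25 * sqrt(2), tolerance = 1e-4)
})

test_that("volume calibration recovers the waist from simulated dye traces", {
  w0s <- sapply(1:5, function(s) {
    vol <- observation_volume()
    cfg <- sim_config(vol = vol, box = 3 * c(vol$w0, vol$w0, vol$z0),
                      dt = 5e-6, duration = 5, background_rate = 200,
                      seed = 300 + s)
    sp <- species_spec(400, 20000, prod(2 * cfg$box) / vol$V_eff)
    cv <- autocorrelate(simulate_trace(sp, cfg))
    suppressWarnings(calibrate_volume(cv, D_ref = 400))$w0
  })
  expect_lt(abs(stats::median(w0s) / 0.25 - 1), 0.1)
})

test_that("derived quantities convert units correctly", {
  vol <- observation_volume(w0 = 0.25)
  cv <- synthesize_acf("D1P", list(N = 2, tau_D1 = 5.2e-4, K = 5, G_inf = 1),
                       default_lag_grid())
  fit <- fit_acf(cv, acf_model("D1P"))
  fit$mean_intensity <- 10000
  dq <- derived_quantities(fit, vol)
  expect_equal(dq$D1, 0.25^2 / (4 * 5.2e-4), tolerance = 1e-4)
  expect_equal(dq$cpm, 10000 / 2, tolerance = 1e-3)
  expect_error(derived_quantities(fit), class = "fcspipe_invalid_parameter")
  # flow conversion v = w0/tau_f
  cvf <- synthesize_acf("D1P_FLOW", list(N = 1, tau_D1 = 5e-3, tau_f = 5e-3,
                                         K = 5, G_inf = 1),
                        default_lag_grid())
  fitf <- fit_acf(cvf, acf_model("D1P_FLOW"))
  dqf <- derived_quantities(fitf, vol)
  expect_equal(dqf$v, 50, tolerance = 1e-3)
  # F2 = 0 means F1 = 1
  cv2 <- synthesize_acf("D2P", list(N = 1, tau_D1 = 5e-4, tau_D2 = 5e-2,
                                    F2 = 0, K = 5, G_inf = 1),
                        default_lag_grid())
  fit2 <- fit_acf(cv2, acf_model("D2P"), init = list(N = 1, tau_D1 = 5e-4,
                                                     tau_D2 = 5e-2, F2 = 0,
                                                     K = 5, G_inf = 1))
  dq2 <- derived_quantities(fit2, vol)
  expect_equal(dq2$F1, 1, tolerance = 1e-5)
  expect_true(dq2$F2_caveat)
})

test_that("fits are invariant under a joint lag-unit rescaling", {
  truth <- list(N = 2, tau_D1 = 4e-4, K = 5, G_inf = 1)
  lags <- default_lag_grid()
  cv_s <- synthesize_acf("D1P", truth, lags)
  cv_ms <- correlation_curve(lags * 1e3, cv_s$G)
  fit_s <- fit_acf(cv_s, acf_model("D1P"))
  fit_ms <- fit_acf(cv_ms, acf_model("D1P"), fit_start_lag = 1e-2)
  expect_equal(fit_ms$params$tau_D1, fit_s$params$tau_D1 * 1e3,
               tolerance = 1e-5)
  expect_equal(fit_ms$params$N, fit_s$params$N, tolerance = 1e-6)
})

test_that("recovery error shrinks as the acquisition grows", {
  vol <- observation_volume()
  n_box <- prod(2 * 5 * c(vol$w0, vol$w0, vol$z0)) / vol$V_eff
  err_at <- function(duration, seeds) {
    sapply(seeds, function(s) {
      cfg <- sim_config(vol = vol, duration = duration, seed = s)
      sp <- species_spec(30, 8000, n_box)
      cv <- autocorrelate(simulate_trace(sp, cfg))
      fit <- suppressWarnings(fit_acf(cv, acf_model("D1P")))
      abs(tau_to_diffusion(fit$params$tau_D1, vol) / 30 - 1)
    })
  }
  short <- err_at(4, 21:23)
  long <- err_at(20, 21:23)
  expect_lte(stats::median(long), stats::median(short))
})

test_that("tidy and glance expose fit and selection results", {
  cv <- synthesize_acf("D1P", list(N = 2, tau_D1 = 1e-3, K = 5, G_inf = 1),
                       default_lag_grid(), noise_sd = 0.003, seed = 2)
  fit <- suppressWarnings(fit_acf(cv, acf_model("D1P")))
  td <- tidy(fit)
  expect_setequal(td$term, c("N", "tau_D1", "G_inf"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_true(gl$converged)
  sel <- suppressWarnings(select_model(cv, list("D1P", "D2P")))
  expect_true(any(tidy(sel)$chosen))
  expect_equal(glance(sel)$chosen, sel$chosen)
})
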