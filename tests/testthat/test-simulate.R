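vol5 <- observation_volume()
small_box <- 3 * c(vol5$w0, vol5$w0, vol5$z0)

test_that("pure background gives Poisson counts at the configured rate", {
  cfg <- sim_config(duration = 10, background_rate = 1000, seed = 5)
  tr <- simulate_trace(NULL, cfg)
  expect_lt(abs(sum(tr$counts) - 1e4), 4 * sqrt(1e4))
})

test_that("a pinned molecule at the focus emits at full brightness", {
  cfg <- sim_config(box = small_box, dt = 1e-4, duration = 5,
                    background_rate = 200, seed = 6)
  sp <- species_spec(0, 5000, 1)
  tr <- simulate_trace(sp, cfg, init_at_origin = TRUE)
  total <- sum(tr$counts)
  expect_lt(abs(total - 5 * 5200), 4 * sqrt(5 * 5200))
  # counts are Poisson: variance close to mean
  expect_lt(abs(stats::var(tr$counts) / mean(tr$counts) - 1), 0.1)
})

test_that("traces are bit-identical across runs with the same seed", {
  sp <- species_spec(10, 3000, 30)
  cfg <- sim_config(box = small_box, duration = 2, seed = 77)
  a <- simulate_trace(sp, cfg)
  b <- simulate_trace(sp, cfg)
  expect_identical(a$counts, b$counts)
  cfg2 <- sim_config(box = small_box, duration = 2, seed = 78)
  expect_false(identical(a$counts, simulate_trace(sp, cfg2)$counts))
})

test_that("detected mean intensity matches the analytic expectation", {
  cfg <- sim_config(box = small_box, duration = 20, background_rate = 300,
                    seed = 8)
  sp <- species_spec(10, 3000, 60)
  tr <- simulate_trace(sp, cfg)
  expected <- expected_signal(sp, cfg)$mean_intensity
  observed <- sum(tr$counts) / attr(tr, "duration")
  expect_lt(abs(observed / expected - 1), 0.05)
})

test_that("telegraph blinking appears in the ACF with the f/(1-f) amplitude", {
  f <- 0.2
  cfg <- sim_config(box = small_box, dt = 4e-6, duration = 24,
                    background_rate = 100, seed = 9)
  sp <- species_spec(5, 16000, 40, triplet_fraction = f, triplet_tau = 2e-5)
  tr <- simulate_trace(sp, cfg)
  cv <- autocorrelate(tr)
  fit <- suppressWarnings(fit_acf(cv, acf_model("D1P_TRIP")))
  expect_true(fit$converged)
  amp <- fit$params$F_trip / (1 + fit$params$F_trip)
  expect_lt(abs(amp - f / (1 - f)), 0.1)
  expect_lt(abs(log10(fit$params$tau_trip / 2e-5)), log10(5))
  # blinking also reduces the mean intensity by the dark fraction
  expected <- expected_signal(sp, cfg)$mean_intensity
  expect_lt(abs(sum(tr$counts) / 24 / expected - 1), 0.08)
})

test_that("configuration invariants are enforced with explicit errors", {
  expect_error(sim_config(box = c(0.1, 0.1, 0.1)),
               class = "fcspipe_config_error")
  cfg <- sim_config(box = small_box, dt = 1e-3)
  expect_error(simulate_trace(species_spec(30, 5000, 10), cfg),
               class = "fcspipe_config_error")
  cfg2 <- sim_config(box = small_box, dt = 1e-5)
  expect_error(
    simulate_trace(species_spec(5, 5000, 10, triplet_fraction = 0.3,
                                triplet_tau = 2e-5), cfg2),
    class = "fcspipe_config_error")
  expect_error(simulate_trace(NULL, sim_config(background_rate = 0)),
               class = "fcspipe_config_error")
})

test_that("synthesized curves follow the model exactly and noise is unbiased", {
  p <- list(N = 2, tau_D1 = 5e-4, K = 5, G_inf = 1)
  lags <- 10^seq(-5, 0, length.out = 60)
  cv <- synthesize_acf("D1P", p, lags)
  expect_equal(cv$G, acf_d1p(lags, 2, 5e-4, 5, 1))
  # noisy draws average to the model
  set.seed(31)
  draws <- replicate(1000, synthesize_acf("D1P", p, lags[c(1, 30, 60)],
                                          noise_sd = 0.05)$G)
  dev <- rowMeans(draws) - acf_d1p(lags[c(1, 30, 60)], 2, 5e-4, 5, 1)
  expect_true(all(abs(dev) < 4 * 0.05 / sqrt(1000)))
})

test_that("a widely separated two-component curve is biphasic at the mid-lag", {
  p <- list(N = 1, tau_D1 = 1e-4, tau_D2 = 1e-2, F2 = 0.4, K = 5, G_inf = 1)
  mid <- sqrt(p$tau_D1 * p$tau_D2)
  g_mid <- synthesize_acf("D2P", p, mid)$G
  expect_gt(g_mid, p$G_inf + 0.9 * p$F2 / p$N)
  expect_lt(g_mid, p$G_inf + 0.6 / p$N)
})

test_that("the regime catalog is reproducible and labeled with ground truth", {
  cat1 <- make_regime_catalog(seed = 3, regimes = c("monomer", "flow"),
                              duration = 2)
  cat2 <- make_regime_catalog(seed = 3, regimes = c("monomer", "flow"),
                              duration = 2)
  expect_identical(cat1$trace[[1]]$counts, cat2$trace[[1]]$counts)
  expect_identical(cat1$trace[[2]]$counts, cat2$trace[[2]]$counts)
  expect_setequal(cat1$regime, c("monomer", "flow"))
  expect_equal(cat1$D1_true[cat1$regime == "monomer"], 30)
  expect_equal(cat1$v_true[cat1$regime == "flow"], 54.5)
  expect_s3_class(cat1$trace[[1]], "intensity_trace")
})

test_that("aggregate-burst traces trip the spike screen", {
  cat_a <- make_regime_catalog(seed = 14, regimes = "aggregate",
                               duration = 12)
  tr <- cat_a$trace[[1]]
  coarse <- rebin_trace(tr, as.integer(round(1e-3 / attr(tr, "bin_width"))))
  sp <- detect_spikes(coarse, k = 5)
  expect_gte(nrow(sp), 1)
  expect_true(attr(sp, "aggregate_suspected"))
})

test_that("fitted particle number scales linearly with concentration", {
  vol <- observation_volume()
  n_box <- prod(2 * 8 * c(vol$w0, vol$w0, vol$z0)) / vol$V_eff
  fits <- lapply(c(0.6, 1.2), function(target) {
    cfg <- sim_config(duration = 15, seed = 40 + round(10 * target))
    sp <- species_spec(30, 8000, target * n_box)
    cv <- autocorrelate(simulate_trace(sp, cfg))
    fit <- suppressWarnings(fit_acf(cv, acf_model("D1P")))
    derived_quantities(fit, vol, background = cfg$background_rate)$N
  })
  ratio <- fits[[2]] / fits[[1]]
  expect_lt(abs(ratio / 2 - 1), 0.15)
})
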