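test_that("one-component diffusion model matches hand arithmetic", {
  # zero-lag amplitude: 1/N + G_inf
  expect_equal(acf_d1p(0, N = 5, tau_D1 = 1e-3), 1.2)
  # large-K limit at tau = tau_D: half amplitude
  expect_equal(acf_d1p(1e-3, N = 1, tau_D1 = 1e-3, K = 1e6, G_inf = 0),
               0.5, tolerance = 1e-6)
  # 0.5 * 1.04^(-1/2) / 2 = 0.2451452
  expect_equal(acf_d1p(1e-3, N = 2, tau_D1 = 1e-3, K = 5, G_inf = 0),
               0.25 / sqrt(1.04), tolerance = 1e-12)
  expect_equal(0.25 / sqrt(1.04), 0.2451452, tolerance = 1e-6)
  # vectorized and finite on a wide grid
  g <- acf_d1p(10^seq(-7, 1, length.out = 50), N = 2, tau_D1 = 1e-3)
  expect_true(all(is.finite(g)))
  expect_error(acf_d1p(1e-3, N = -1, tau_D1 = 1e-3),
               class = "fcspipe_invalid_parameter")
  expect_error(acf_d1p(1e-3, N = 1, tau_D1 = 0),
               class = "fcspipe_invalid_parameter")
})

test_that("triplet prefactor follows the F/(1+F) parameterization", {
  # F_trip = 0 reduces exactly to the plain model
  tau <- 10^seq(-6, 0, length.out = 40)
  expect_equal(acf_d1p_triplet(tau, 2, 0, 1e-5, 1e-3, 5, 1),
               acf_d1p(tau, 2, 1e-3, 5, 1))
  # prefactor vanishes at lags >> tau_trip
  expect_equal(acf_d1p_triplet(1e-3, 1, 0.5, 1e-5, 1e-3, 5, 0),
               acf_d1p(1e-3, 1, 1e-3, 5, 0), tolerance = 1e-15)
  # hand arithmetic: (1 + 0.2 e^-1) (1.01)^-1 (1.0004)^(-1/2)
  hand <- (1 + (0.25 / 1.25) * exp(-1)) * (1 / 1.01) * (1 + 4e-4)^(-0.5)
  expect_equal(acf_d1p_triplet(1e-5, 1, 0.25, 1e-5, 1e-3, 5, 0),
               hand, tolerance = 1e-12)
  expect_equal(hand, 1.062734, tolerance = 1e-6)
})

test_that("two-component model reduces and symmetrizes correctly", {
  tau <- 10^seq(-6, 0, length.out = 40)
  # F2 = 0: second component vanishes
  expect_equal(acf_d2p(tau, 2, 1e-3, 1e-2, 0, 5, 1),
               acf_d1p(tau, 2, 1e-3, 5, 1))
  # equal diffusion times: components merge for any F2
  expect_equal(acf_d2p(tau, 2, 1e-3, 1e-3, 0.37, 5, 1),
               acf_d1p(tau, 2, 1e-3, 5, 1))
  # label symmetry
  expect_equal(acf_d2p(tau, 2, 1e-3, 1e-2, 1, 5, 1),
               acf_d2p(tau, 2, 1e-2, 1e-2, 0, 5, 1))
  expect_error(acf_d2p(1e-3, 2, 1e-3, 1e-2, 1.2, 5, 1),
               class = "fcspipe_invalid_parameter")
})

test_that("diffusion-plus-flow model matches its limits and hand value", {
  tau <- 10^seq(-6, -1, length.out = 30)
  # tau_f -> infinity: flow factor -> 1
  expect_equal(acf_flow_diffusion(tau, 1, 1e-3, 1e6, 5, 0),
               acf_d1p(tau, 1, 1e-3, 5, 0), tolerance = 1e-10)
  # tau_D -> infinity: pure Gaussian decay
  expect_equal(acf_flow_diffusion(1e-3, 1, 1e9, 2e-3, 5, 0),
               exp(-0.25), tolerance = 1e-6)
  expect_equal(acf_flow(1e-3, 1, 2e-3, 0), exp(-0.25))
  # hand arithmetic: 0.5 * 1.04^(-1/2) * exp(-0.25/2) = 0.4326800
  expect_equal(acf_flow_diffusion(1e-3, 1, 1e-3, 2e-3, 5, 0),
               0.5 / sqrt(1.04) * exp(-0.125), tolerance = 1e-12)
  expect_equal(0.5 / sqrt(1.04) * exp(-0.125), 0.4326800, tolerance = 1e-6)
  expect_error(acf_flow_diffusion(1e-3, 1, 1e-3, -1, 5, 0),
               class = "fcspipe_invalid_parameter")
})

test_that("model curves decay monotonically and have the right amplitude", {
  set.seed(11)
  tau <- 10^seq(-7, 0.5, length.out = 200)
  for (i in 1:25) {
    p <- random_valid_params()
    for (id in c("D1P", "D1P_TRIP", "D2P", "D2P_TRIP", "D1P_FLOW", "FLOW")) {
      g <- acf_eval(id, tau, p)
      expect_true(all(diff(g) <= 1e-12), label = paste(id, "monotone"))
      amp0 <- acf_eval(id, 0, p) - p$G_inf
      expected_amp <- if (id %in% c("D1P_TRIP", "D2P_TRIP")) {
        (1 / p$N) * (1 + p$F_trip / (1 + p$F_trip))
      } else 1 / p$N
      expect_equal(amp0, expected_amp, tolerance = 1e-12)
    }
  }
})

test_that("reduction identities hold on random parameter draws", {
  set.seed(12)
  tau <- 10^seq(-6, 0, length.out = 60)
  for (i in 1:50) {
    p <- random_valid_params()
    d1 <- acf_d1p(tau, p$N, p$tau_D1, p$K, p$G_inf)
    expect_equal(acf_d1p_triplet(tau, p$N, 0, p$tau_trip, p$tau_D1, p$K,
                                 p$G_inf), d1, tolerance = 1e-12)
    expect_equal(acf_d2p(tau, p$N, p$tau_D1, p$tau_D2, 0, p$K, p$G_inf),
                 d1, tolerance = 1e-12)
    expect_equal(acf_d2p(tau, p$N, p$tau_D1, p$tau_D1, p$F2, p$K, p$G_inf),
                 d1, tolerance = 1e-12)
    expect_equal(acf_flow_diffusion(tau, p$N, p$tau_D1, 1e9, p$K, p$G_inf),
                 d1, tolerance = 1e-10)
  }
})

test_that("model evaluation is invariant to a joint time rescaling", {
  set.seed(13)
  tau <- 10^seq(-6, 0, length.out = 30)
  for (i in 1:10) {
    p <- random_valid_params()
    ps <- p
    for (nm in c("tau_trip", "tau_D1", "tau_D2", "tau_f")) {
      ps[[nm]] <- p[[nm]] * 1e3
    }
    for (id in c("D1P_TRIP", "D2P", "D1P_FLOW")) {
      expect_equal(acf_eval(id, tau, p), acf_eval(id, tau * 1e3, ps),
                   tolerance = 1e-12)
    }
  }
})

test_that("parameter container enforces its invariants", {
  p <- acf_params(N = 2, tau_D1 = 1e-3, tau_D2 = 1e-2, F2 = 0.4,
                  F_trip = 0.2, tau_trip = 1e-5)
  expect_s3_class(p, "acf_params")
  expect_error(acf_params(N = 0), class = "fcspipe_invalid_parameter")
  expect_error(acf_params(N = 1, tau_D1 = 1e-2, tau_D2 = 1e-3),
               class = "fcspipe_invalid_parameter")
  expect_error(acf_params(N = 1, F2 = 1.5),
               class = "fcspipe_invalid_parameter")
  expect_error(acf_params(N = 1, tau_D1 = 1e-5, tau_trip = 1e-3),
               class = "fcspipe_invalid_parameter")
  expect_error(acf_params(N = 1, K = 0.5),
               class = "fcspipe_invalid_parameter")
  # model spec: free/fixed must be disjoint and cover the symbols
  m <- acf_model("D2P", fixed = list(K = 5))
  expect_setequal(m$free, c("N", "tau_D1", "tau_D2", "F2", "G_inf"))
  expect_error(acf_model("D1P", free = c("N", "tau_D1"),
                         fixed = list(tau_D1 = 1e-3)),
               class = "fcspipe_invalid_parameter")
})

test_that("diffusion-time conversions and displacement follow the standard relations", {
  vol <- observation_volume(w0 = 0.25)
  expect_equal(tau_to_diffusion(39.0625e-6, vol), 400)
  expect_equal(diffusion_to_tau(tau_to_diffusion(1.7e-4, vol), vol), 1.7e-4)
  # doubling w0 quadruples D at fixed tau_D
  expect_equal(tau_to_diffusion(1e-3, observation_volume(w0 = 0.5)),
               4 * tau_to_diffusion(1e-3, vol))
  expect_equal(rms_displacement(30, 1), sqrt(60))
  expect_equal(rms_displacement(0, 5), 0)
  expect_equal(rms_displacement(1, 1), sqrt(2))
  expect_error(rms_displacement(-1, 1), class = "fcspipe_invalid_parameter")
  # observation volume geometry
  v <- observation_volume(w0 = 0.25, z0 = 1.25)
  expect_equal(v$K, 5)
  expect_equal(v$V_eff, pi^1.5 * 0.25^2 * 1.25)
})
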