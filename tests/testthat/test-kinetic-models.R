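test_that("kinetic_params validates its invariants and the model/K_M link", {
  expect_error(kinetic_params(kp_kn = 0, kp_k2 = 1), "kp_kn")
  expect_error(kinetic_params(kp_kn = 1, kp_k2 = -1), "kp_k2")
  expect_error(kinetic_params(kp_kn = 1, kp_k2 = 1, n_c = 0.5), "n_c")
  expect_error(kinetic_params(kp_kn = 1, kp_k2 = 1, K_M = 0), "K_M")
  expect_error(kinetic_params(kp_kn = 1, kp_k2 = 1, K_M = 5,
                              model = "single_step"), "inconsistent")
  expect_identical(kinetic_params(kp_kn = 1, kp_k2 = 1)$model, "single_step")
  expect_identical(kinetic_params(kp_kn = 1, kp_k2 = 1, K_M = 5)$model,
                   "multi_step")
  # raw-constant aliasing folds into the products
  p <- kinetic_params(k_n = 2, k_plus = 3, k_2 = 5)
  expect_equal(p$kp_kn, 6)
  expect_equal(p$kp_k2, 15)
})

test_that("parameters survive a JSON round-trip, including infinite K_M", {
  p1 <- kinetic_params(kp_kn = 3.5e-7, kp_k2 = 7e-5, K_M = 18)
  p2 <- params_from_json(params_to_json(p1))
  expect_equal(p2, p1)
  ps <- kinetic_params(kp_kn = 1e-4, kp_k2 = 10)
  expect_match(params_to_json(ps), "\"inf\"")
  expect_equal(params_from_json(params_to_json(ps)), ps)
})

test_that("effective rates match their defining algebra", {
  # K_M -> Inf multi-step equals single-step with the same constants
  ps <- kinetic_params(kp_kn = 2e-6, kp_k2 = 3e-4)
  pm <- kinetic_params(kp_kn = 2e-6, kp_k2 = 3e-4, K_M = 1e30)
  expect_equal(effective_rates(pm, 4), effective_rates(ps, 4),
               tolerance = 1e-12)
  # at m0^n2 = K_M the saturation factor is 2: kappa drops by sqrt(2)
  pk <- kinetic_params(kp_kn = 2e-6, kp_k2 = 3e-4, K_M = 16)
  expect_equal(effective_rates(pk, 4)$kappa,
               effective_rates(ps, 4)$kappa / sqrt(2))
  # unit constants, m0 = 1: lambda = kappa = sqrt(2)
  p1 <- kinetic_params(kp_kn = 1, kp_k2 = 1)
  expect_equal(effective_rates(p1, 1), list(lambda = sqrt(2), kappa = sqrt(2)))
  expect_error(effective_rates(p1, -1), "m0")
})

test_that("mass fraction starts at zero, saturates at one, stays in [0,1]", {
  p <- default_tht_params()
  t <- seq(0, 40, length.out = 200)
  for (f in list(mass_fraction_closed, mass_fraction_ode)) {
    M <- f(p, t, 3)
    expect_equal(M[1], 0, tolerance = 1e-8)
    expect_true(all(M >= 0 & M <= 1))
    expect_true(all(diff(M) >= -1e-9))
    expect_equal(M[length(M)], 1, tolerance = 1e-4)
  }
  # very large kappa*t exercises the asymptotic branch without overflow
  expect_equal(mass_fraction_closed(p, c(0, 1e6), 3)[2], 1)
})

test_that("time-rescaling symmetry: k -> a k rescales the curve to t/a", {
  p <- kinetic_params(k_n = 1e-3, k_plus = 0.1, k_2 = 30, K_M = 20)
  a <- 10
  pa <- kinetic_params(k_n = a * 1e-3, k_plus = a * 0.1, k_2 = a * 30,
                       K_M = 20)
  t <- seq(0, 30, length.out = 150)
  expect_equal(mass_fraction_ode(pa, t / a, 3), mass_fraction_ode(p, t, 3),
               tolerance = 1e-6)
  expect_equal(mass_fraction_closed(pa, t / a, 3),
               mass_fraction_closed(p, t, 3), tolerance = 1e-12)
  # in product space, doubling both products shortens tau by sqrt(2)
  p2 <- kinetic_params(kp_kn = 2 * p$kp_kn, kp_k2 = 2 * p$kp_k2, K_M = 20)
  expect_equal(model_halftime(p2, 3), model_halftime(p, 3) / sqrt(2),
               tolerance = 1e-5)
})

test_that("integrator reproduces the frozen high-accuracy half time", {
  # frozen from a rtol = 1e-12 lsoda run on a dense grid (4001 points)
  p <- kinetic_params(kp_kn = 1e-4, kp_k2 = 10)
  tau_frozen <- 0.58422184
  t <- seq(0, 2, length.out = 801)
  M <- mass_fraction_ode(p, t, 3)
  i <- which(M >= 0.5)[1]
  tau <- approx(M[(i - 1):i], t[(i - 1):i], xout = 0.5)$y
  expect_equal(tau, tau_frozen, tolerance = 1e-4)
  # the closed form agrees with the ODE half time within 1%
  expect_equal(model_halftime(p, 3), tau_frozen, tolerance = 0.01)
})

test_that("closed form tracks the ODE oracle in its accuracy domain", {
  max_dev <- function(draws) max(vapply(draws, function(d) {
    t <- seq(0, 15 / d$kappa, length.out = 120)
    max(abs(mass_fraction_closed(d$params, t, d$m0) -
              mass_fraction_ode(d$params, t, d$m0)))
  }, numeric(1)))
  # unsaturated, strongly secondary-dominated (kappa/lambda >= 20):
  # agreement better than 1e-2 everywhere on kappa*t in [0, 15]
  single <- draw_kinetic_params(30, seed = 11, ratio_min = 20,
                                ratio_max = 1000, single_only = TRUE)
  expect_lt(max_dev(single), 1e-2)
  # with saturation up to m0^n2/K_M = 10 the first-order rate law is a
  # few-percent approximation (documented); bound it at 7e-2
  mixed <- draw_kinetic_params(30, seed = 12, ratio_min = 20,
                               ratio_max = 1000)
  expect_lt(max_dev(mixed), 7e-2)
})

test_that("multi-step converges pointwise to single-step as K_M grows", {
  ps <- kinetic_params(kp_kn = 1.26e-3, kp_k2 = 0.252)
  pm <- kinetic_params(kp_kn = 1.26e-3, kp_k2 = 0.252, K_M = 9 * 1e6)
  t <- seq(0, 10, length.out = 300)
  expect_lt(max(abs(mass_fraction_closed(pm, t, 3) -
                      mass_fraction_closed(ps, t, 3))), 1e-6)
})

test_that("model_halftime matches a dense-grid bisection oracle", {
  p <- default_tht_params()
  for (m0 in c(1, 3, 9)) {
    tau <- model_halftime(p, m0)
    tg <- seq(0, 4 * tau, length.out = 20001)
    M <- mass_fraction_closed(p, tg, m0)
    i <- which(M >= 0.5)[1]
    tau_grid <- approx(M[(i - 1):i], tg[(i - 1):i], xout = 0.5)$y
    expect_equal(tau, tau_grid, tolerance = 1e-4)
  }
  # a curve that cannot reach 0.5 within the horizon errors out
  expect_error(model_halftime(p, 3, horizon = 0.01), "horizon")
})

test_that("half-time scaling exponents hit the mechanistic limits", {
  m0 <- 1:9
  gamma_of <- function(p) {
    taus <- vapply(m0, function(m) model_halftime(p, m), numeric(1))
    scaling_exponent(m0, taus)$gamma
  }
  # the limits hold where secondary nucleation stays dominant, so primary
  # nucleation is kept weak (kappa/lambda > 100 across the series)
  # unsaturated n2 = 2: gamma ~ -(n2+1)/2 = -1.5
  g_unsat <- gamma_of(kinetic_params(kp_kn = 1e-5, kp_k2 = 0.252))
  expect_gt(g_unsat, -1.6); expect_lt(g_unsat, -1.4)
  # strongly saturated (m0^n2/K_M in [100, 8100]): gamma ~ -1/2
  g_sat <- gamma_of(kinetic_params(kp_kn = 1e-5, kp_k2 = 2000, K_M = 0.01))
  expect_gt(g_sat, -0.7); expect_lt(g_sat, -0.4)
  # intermediate K_M interpolates, and gamma is monotone in K_M
  gs <- vapply(c(0.1, 1, 8.24, 100, 1e4),
               function(km) gamma_of(kinetic_params(kp_kn = 1e-5,
                                                    kp_k2 = 0.252,
                                                    K_M = km)),
               numeric(1))
  expect_true(all(diff(gs) < 0))
  expect_gt(gs[3], -1.5); expect_lt(gs[3], -0.5)
})
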