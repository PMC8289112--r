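test_that("energy closed forms and brute-force oracle agree", {
  p <- mild_params()
  gr <- locust_grid(L = 12, n = 64)
  expect_equal(aggregation_energy(rep(0, 64), 0.5, p, gr), 0)

  # uniform field closed form (zero-mode multiplier of the sampled kernel;
  # it equals the continuum hat(Q_g)(0) up to O(dx^2) kink quadrature)
  a <- 0.8; cb <- 0.3
  qg0 <- kernel_multiplier(social_potential("gregarious", p), gr)[1]
  expect_equal(qg0, potential_hat(social_potential("gregarious", p), 0),
               tolerance = 2e-2)
  dec <- p$D * exp(-cb)
  expected <- gr$L * (0.5 * a^2 * qg0 + dec * p$gamma * a^3 / 6 +
                      dec * (a * log(a) - a))
  expect_equal(aggregation_energy(rep(a, 64), cb, p, gr), expected,
               tolerance = 1e-12)

  # random field vs O(n^2) wrapped double-sum oracle
  set.seed(11)
  g <- stats::runif(64, 0.1, 2)
  conv_slow <- brute_convolve(g, social_potential("gregarious", p), gr)
  E_slow <- sum(0.5 * g * conv_slow + dec * p$gamma * g^3 / 6 +
                dec * (g * log(g) - g)) * gr$dx
  expect_equal(aggregation_energy(g, cb, p, gr), E_slow, tolerance = 1e-6)
  expect_error(aggregation_energy(rep(-1, 64), 0, p, gr), "negative")
})

test_that("large-mass aggregate density and support match hand evaluations", {
  p <- mild_params()
  lm0 <- large_mass_limit(20, 0, p)
  expect_equal(lm0$g_max, 4.363541, tolerance = 1e-6)
  lm1 <- large_mass_limit(20, 1, p)
  expect_equal(lm1$g_max, 11.88828, tolerance = 1e-6)
  # food raises the maximum density
  expect_gt(lm1$g_max, lm0$g_max)
  # algebraic identity g_max * support = M, any admissible inputs
  for (M in c(0.5, 3, 77)) {
    lm <- large_mass_limit(M, 0.4, p)
    expect_equal(lm$g_max * lm$support, M)
  }
  # repulsion-dominated kernel refuses
  p_rep <- suppressWarnings(locust_params(D = 0.01, gamma = 60, R_s = 0.25,
                                          r_s = 1, R_g = 3, r_g = 0.5,
                                          A_g = 1, k = 1, delta = 1,
                                          kappa = 0))
  expect_error(large_mass_limit(1, 0, p_rep), "attraction")
  # strong diffusion kills the real root
  p_diff <- suppressWarnings(locust_params(D = 10, gamma = 60, R_s = 0.25,
                                           r_s = 1, R_g = 0.25, r_g = 0.5,
                                           A_g = 1, k = 1, delta = 1,
                                           kappa = 0))
  expect_error(large_mass_limit(1, 0, p_diff), "discriminant")
})

test_that("small-mass aggregate matches hand values and the M^(2/3) scaling", {
  p <- mild_params()
  sm <- small_mass_limit(0.1, 0, p)
  expect_equal(sm$g_max, 0.0109375^(1 / 3), tolerance = 1e-12)  # 0.22196...
  expect_equal(sm$g_max, 0.22196, tolerance = 1e-4)
  expect_equal(sm$support, 0.58273, tolerance = 1e-4)
  expect_equal(beta(2 / 3, 1 / 2), 2.58712, tolerance = 1e-5)
  sm2 <- small_mass_limit(0.2, 0, p)
  expect_equal(sm2$g_max / sm$g_max, 2^(2 / 3), tolerance = 1e-12)
})

test_that("formation threshold matches hand values and its food/density trends", {
  p <- sym_params()
  expect_equal(phi_threshold(1, 0, p), 0.53692, tolerance = 1e-5)
  # saturated-food limit: 2 R_s r_s / (2 A_g - 2 R_g r_g + 2 R_s r_s)
  expect_equal(phi_threshold(1, 40, p),
               2 * p$R_s * p$r_s /
                 (2 * p$A_g - 2 * p$R_g * p$r_g + 2 * p$R_s * p$r_s),
               tolerance = 1e-9)
  expect_equal(phi_threshold(1, 40, p), 0.37935, tolerance = 1e-5)
  # strictly decreasing in food at fixed density
  cb <- seq(0, 3, by = 0.25)
  expect_true(all(diff(phi_threshold(1, cb, p)) < 0))
  # increasing in density above gamma^(-1/2)
  rho <- seq(1.2 / sqrt(p$gamma) + 0.05, 2, length.out = 30)
  thr <- vapply(rho, phi_threshold, 1, c_bar = 0, params = p)
  expect_true(all(diff(thr) > 0))
  # non-positive denominator signals stability at all fractions
  p_rep <- suppressWarnings(locust_params(D = 1, gamma = 1, R_s = 0.1,
                                          r_s = 1, R_g = 3, r_g = 0.9,
                                          A_g = 1, k = 1, delta = 1,
                                          kappa = 0))
  expect_equal(phi_threshold(1, 0, p_rep), Inf)
})

test_that("upper density bound: closed form, defining property, asymptotics", {
  p <- mild_params()
  ru <- rho_upper_bound(0, p)
  expect_equal(ru, 2.91094, tolerance = 1e-5)
  # defining property: the threshold equals 1 there
  expect_equal(phi_threshold(ru, 0, p), 1, tolerance = 1e-10)
  # about 2/3 of the large-mass maximum in the weak-diffusion regime
  expect_equal(ru / large_mass_limit(1, 0, p)$g_max, 2 / 3, tolerance = 1e-3)
  # asymptotic agreement as (D e^-c)^2 gamma / net^2 -> 0
  for (ratio in c(1e-2, 1e-4)) {
    net <- 0.875
    D_small <- sqrt(ratio * net^2 / 60)
    ps <- suppressWarnings(locust_params(D = D_small, gamma = 60, R_s = 0.25,
                                         r_s = 1, R_g = 0.25, r_g = 0.5,
                                         A_g = 1, k = 1, delta = 1,
                                         kappa = 0))
    expect_equal(rho_upper_bound(0, ps) / large_mass_limit(1, 0, ps)$g_max,
                 2 / 3, tolerance = ratio)
  }
  p_diff <- suppressWarnings(locust_params(D = 10, gamma = 60, R_s = 0.25,
                                           r_s = 1, R_g = 0.25, r_g = 0.5,
                                           A_g = 1, k = 1, delta = 1,
                                           kappa = 0))
  expect_error(rho_upper_bound(0, p_diff), "no instability window")
})

test_that("implicit formation condition reproduces the hand-checked cases", {
  p <- sym_params()
  r08 <- formation_condition(0.8, 0, p)
  expect_false(r08$forms)
  expect_equal(r08$phi_ss, 0.48742, tolerance = 1e-4)
  expect_equal(r08$phi_threshold, 0.50556, tolerance = 1e-4)
  expect_equal(r08$t_star, Inf)

  r10 <- formation_condition(1, 0, p)
  expect_true(r10$forms)
  expect_equal(r10$phi_ss, 0.57740, tolerance = 1e-4)
  expect_true(is.finite(r10$t_star))

  # increasing food never flips formation off
  for (rho in c(0.8, 1, 1.2)) {
    verdicts <- vapply(c(0, 0.5, 1, 2, 4), function(cb)
      formation_condition(rho, cb, p)$forms, logical(1))
    expect_true(all(diff(verdicts) >= 0))  # FALSE -> TRUE only
  }
})

test_that("time to formation inverts the homogeneous solution exactly", {
  p <- sym_params()
  expect_equal(time_to_formation(1, 1, p), 1.1972, tolerance = 1e-3)
  # consistency: g(t*) = phi_threshold * rho_bar whenever finite
  for (case_i in seq_len(3)) {
    rho <- c(1, 1.1, 1.3)[case_i]; cb <- c(1, 0.5, 0)[case_i]
    ts <- time_to_formation(rho, cb, p)
    expect_true(is.finite(ts))
    expect_equal(homogeneous_g(ts, rho, p),
                 phi_threshold(rho, cb, p) * rho, tolerance = 1e-10)
  }
  # boundary: threshold at the steady fraction -> never crosses
  expect_equal(time_to_formation(0.8, 0, p), Inf)
})

test_that("stability_table maps the phase boundary over a small range", {
  p <- sym_params()
  tab <- stability_table(c(0.8, 1, 1.2), c(0, 1), p)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$forms == (tab$phi_ss > tab$phi_threshold)))
  expect_true(all(is.finite(tab$t_star) == tab$forms))
})
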