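test_that("compiled rhs agrees with the R reference implementation", {
  p <- sym_params()
  gr <- locust_grid(3 / 0.14, 64)
  st <- make_initial_state(locust_ic(1.1, seed = 2), food_ic(2, omega = 20),
                           gr)
  ref <- locust_rhs(st, p, gr)
  qg <- kernel_multiplier(social_potential("gregarious", p), gr)
  qs <- kernel_multiplier(social_potential("solitarious", p), gr)
  y <- c(st$s, st$g, st$c)
  fast <- locustform:::.rhs_cpp(y, unclass(p), gr$n, gr$dx, qg, qs,
                                FALSE, FALSE, NULL)
  scale <- max(abs(fast))
  expect_lt(max(abs(c(ref$ds, ref$dg, ref$dc) - fast)) / scale, 1e-12)

  # and on a non-power-of-two grid (Armadillo FFT fallback)
  gr2 <- locust_grid(3 / 0.14, 96)
  st2 <- make_initial_state(locust_ic(1.1, seed = 2), food_ic(2, omega = 20),
                            gr2)
  ref2 <- locust_rhs(st2, p, gr2)
  qg2 <- kernel_multiplier(social_potential("gregarious", p), gr2)
  qs2 <- kernel_multiplier(social_potential("solitarious", p), gr2)
  fast2 <- locustform:::.rhs_cpp(c(st2$s, st2$g, st2$c), unclass(p), gr2$n,
                                 gr2$dx, qg2, qs2, FALSE, FALSE, NULL)
  expect_lt(max(abs(c(ref2$ds, ref2$dg, ref2$dc) - fast2)) / max(abs(fast2)),
            1e-12)
})

test_that("rhs reduces to kinetics on uniform states and conserves mass discretely", {
  p <- asym_params()
  gr <- locust_grid(3 / 0.14, 32)
  st <- locust_state(0.3, 0.2, 0.7, gr)
  r <- locust_rhs(st, p, gr)
  K <- kinetics_term(0.3, 0.2, p)
  expect_equal(r$ds, rep(K$ds, 32), tolerance = 1e-12)
  expect_equal(r$dg, rep(K$dg, 32), tolerance = 1e-12)
  expect_equal(r$dc, rep(-p$kappa * 0.7 * 0.5, 32))
  r0 <- locust_rhs(st, p, gr, freeze_kinetics = TRUE, freeze_food = TRUE)
  expect_equal(r0$ds, rep(0, 32), tolerance = 1e-14)
  expect_equal(r0$dc, rep(0, 32))

  # discrete conservation on arbitrary states: telescoping + antisymmetry
  set.seed(5)
  for (i in 1:5) {
    st_r <- locust_state(stats::runif(32, 0, 2), stats::runif(32, 0, 2),
                         stats::runif(32, 0, 1), gr)
    r <- locust_rhs(st_r, p, gr)
    expect_lt(abs(sum(r$ds + r$dg) * gr$dx), 1e-10)
  }
  # non-finite states are named, not silently propagated
  stN <- locust_state(1, 1, 0, gr)
  stN$s[5] <- NaN
  expect_error(locust_rhs(stN, p, gr), "non-finite")
})

test_that("pure advection translates a pulse at the prescribed speed", {
  # velocity override + D ~ 0: method-of-characteristics oracle
  p_adv <- suppressWarnings(locust_params(
    D = 1e-14, gamma = 1e-14, R_s = 1e-14, r_s = 1, R_g = 1e-14, r_g = 0.5,
    A_g = 1e-14, k = 1, delta = 1, kappa = 0))
  gr <- locust_grid(10, 256)
  g0 <- exp(-((gr$x - 3) / 0.4)^2)
  st <- locust_state(0, g0, 0, gr)
  v <- 1.5; t_end <- 2
  tr <- simulate_locusts(st, p_adv, gr,
                         solver_config(t_end = t_end,
                                       output_times = c(0, t_end),
                                       freeze_kinetics = TRUE,
                                       freeze_food = TRUE),
                         velocity_override = v)
  com0 <- centre_of_mass(tr$snapshots[[1]], gr)
  com1 <- centre_of_mass(tr$snapshots[[2]], gr)
  drift <- (com1 - com0) %% gr$L
  expect_equal(drift, (v * t_end) %% gr$L, tolerance = 0.01 * v * t_end)
  # first-order smearing: peak decays but mass is conserved
  expect_lt(max(tr$snapshots[[2]]$g), max(g0))
  expect_equal(total_mass(tr$snapshots[[2]], gr), total_mass(st, gr),
               tolerance = 1e-12)
})

test_that("integration matches deSolve's Dormand-Prince on a small case", {
  skip_if_not_installed("deSolve")
  p <- mild_params()
  gr <- locust_grid(12, 32)
  st <- make_initial_state(locust_ic(0.9, seed = 4), food_ic(1, omega = 30),
                           gr)
  cfg <- solver_config(t_end = 0.5, output_times = c(0, 0.25, 0.5),
                       rtol = 1e-9, atol = 1e-12)
  tr <- simulate_locusts(st, p, gr, cfg)
  ode_rhs <- function(t, y, parms) {
    # clamp: deSolve trial steps may probe transiently negative densities,
    # outside the model domain; the accepted solution stays positive
    y <- pmax(y, 0)
    sti <- structure(list(t = t, s = y[1:32], g = y[33:64], c = y[65:96]),
                     class = "locust_state")
    r <- locust_rhs(sti, p, gr)
    list(c(r$ds, r$dg, r$dc))
  }
  ref <- deSolve::ode(c(st$s, st$g, st$c), times = c(0, 0.25, 0.5),
                      func = ode_rhs, parms = NULL, method = "ode45",
                      rtol = 1e-9, atol = 1e-12)
  final <- tr$snapshots[[3]]
  expect_equal(c(final$s, final$g, final$c), unname(ref[3, -1]),
               tolerance = 1e-7)
})

test_that("homogeneous runs reproduce the closed-form kinetics and food decay", {
  gr <- locust_grid(3 / 0.14, 16)
  for (preset in c("symmetric", "asymmetric")) {
    p <- preset_params(preset)
    rho <- if (preset == "symmetric") 1 else 0.4
    st <- locust_state(rho, 0, 0.5, gr)
    cfg <- solver_config(t_end = 12.5, output_times = c(0, 1, 5, 12.5),
                         rtol = 1e-8, atol = 1e-11, freeze_food = TRUE)
    tr <- simulate_locusts(st, p, gr, cfg)
    g_num <- vapply(tr$snapshots, function(s) s$g[1], 1)
    expect_equal(g_num, homogeneous_g(c(0, 1, 5, 12.5), rho, p),
                 tolerance = 1e-6, info = preset)
    # uniformity is preserved exactly
    expect_equal(sd(tr$snapshots[[4]]$g), 0, tolerance = 1e-10)
  }
  # food decays exponentially under a uniform population
  p <- sym_params()
  st <- locust_state(1, 0, 0.8, gr)
  cfg <- solver_config(t_end = 8, output_times = c(0, 2, 8),
                       rtol = 1e-8, atol = 1e-11)
  tr <- simulate_locusts(st, p, gr, cfg)
  c_num <- vapply(tr$snapshots, function(s) s$c[1], 1)
  expect_equal(c_num, 0.8 * exp(-p$kappa * 1 * c(0, 2, 8)), tolerance = 1e-6)
})

test_that("energy decays along a kinetics-off pure-gregarious trajectory", {
  p <- mild_params()
  gr <- locust_grid(12, 64)
  set.seed(9)
  g0 <- pmax(1 + 0.3 * stats::rnorm(64), 0)
  cb <- 0.4
  st <- locust_state(0, g0, cb, gr)
  cfg <- solver_config(t_end = 3, output_times = seq(0, 3, by = 0.25),
                       freeze_kinetics = TRUE, freeze_food = TRUE)
  tr <- simulate_locusts(st, p, gr, cfg)
  E <- vapply(tr$snapshots, function(s) aggregation_energy(s$g, cb, p, gr), 1)
  expect_true(all(diff(E) <= 1e-8))
})

test_that("centre of mass is preserved under uniform constant food", {
  # skewed compact blob relaxing to a symmetric aggregate; the linear first
  # moment is the conserved quantity, and for mass far from the seam the
  # circular mean tracks it to O(1/L^2)
  p <- mild_params()
  gr <- locust_grid(20, 128)
  g0 <- exp(-((gr$x - 10) / 0.6)^2) * (1 + 0.4 * tanh(gr$x - 10))
  st <- locust_state(0.1, g0, 0.3, gr)
  cfg <- solver_config(t_end = 2, output_times = seq(0, 2, by = 0.5),
                       freeze_food = TRUE)
  tr <- simulate_locusts(st, p, gr, cfg)
  coms <- tr$diagnostics$com
  expect_lt(max(abs(coms - coms[1])), 1e-3 * gr$L)
  # the plain first moment is conserved at least as tightly
  lin <- vapply(tr$snapshots,
                function(s) sum((s$s + s$g) * gr$x) / sum(s$s + s$g), 1)
  expect_lt(max(abs(lin - lin[1])), 1e-3 * gr$L)
})

test_that("trajectory bookkeeping: diagnostics, snapshot I/O, print", {
  p <- mild_params()
  gr <- locust_grid(12, 32)
  st <- make_initial_state(locust_ic(1, seed = 1), food_ic(1, omega = 25), gr)
  tr <- simulate_locusts(st, p, gr,
                         solver_config(t_end = 1,
                                       output_times = c(0, 0.5, 1)))
  expect_equal(tr$diagnostics$t, c(0, 0.5, 1))
  expect_true(all(diff(tr$diagnostics$food_total) <= 1e-12))
  expect_output(print(tr), "Locust trajectory")

  tmp <- withr::local_tempfile(fileext = ".txt")
  write_snapshot(tr$snapshots[[3]], gr, tmp, params = p)
  lines <- readLines(tmp)
  expect_match(lines[1], "^# t=1")
  dat <- utils::read.table(tmp, skip = 2)
  expect_equal(dat[[1]], gr$x)
  expect_equal(dat[[3]], tr$snapshots[[3]]$g, tolerance = 1e-12)

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_diagnostics(tr, tmp2)
  expect_equal(utils::read.csv(tmp2)$mass, tr$diagnostics$mass)
})
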