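#' Solver configuration
#'
#' Settings for the adaptive method-of-lines integration. Defaults are
#' `rtol = 1e-6`, `atol = 1e-9` with an embedded Dormand-Prince 5(4) pair;
#' the explicit scheme's stable step is usually set by the nonlinear
#' diffusion, so tolerances mainly control the smooth components.
#' `freeze_kinetics` switches the phase transitions off (used for the
#' gradient-flow and stability experiments) and `freeze_food` forces
#' \eqn{\kappa = 0} (non-depleting food).
#'
#' @param rtol,atol relative and absolute step-error tolerances (> 0).
#' @param t_end final time.
#' @param output_times snapshot times within `[0, t_end]`; defaults to 26
#'   evenly spaced times. Always augmented with 0 and sorted.
#' @param freeze_kinetics,freeze_food logical switches (see above).
#' @param max_step optional cap on the step size (`Inf` to disable).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(t_end, rtol = 1e-6, atol = 1e-9,
                          output_times = NULL, freeze_kinetics = FALSE,
                          freeze_food = FALSE, max_step = Inf) {
  stopifnot(rtol > 0, atol > 0, t_end > 0, max_step > 0)
  if (is.null(output_times)) output_times <- seq(0, t_end, length.out = 26L)
  output_times <- sort(unique(c(0, output_times)))
  if (any(output_times < 0) || any(output_times > t_end + 1e-12))
    stop("output_times must lie within [0, t_end]", call. = FALSE)
  structure(list(rtol = rtol, atol = atol, t_end = t_end,
                 output_times = output_times,
                 freeze_kinetics = isTRUE(freeze_kinetics),
                 freeze_food = isTRUE(freeze_food),
                 max_step = max_step),
            class = "solver_config")
}

#' Semi-discrete right-hand side of the model
#'
#' Reference evaluation of the conservative finite-volume space
#' discretisation: for each population the update is
#' \eqn{du_i/dt = -(F_{i+1/2} - F_{i-1/2})/dx + K_u} with interface flux
#' \eqn{F = F_{adv} + F_{diff}}, first-order upwind advection
#' \eqn{F_{adv} = v^+ u_i + v^- u_{i+1}} using the velocities of
#' [velocity_fields()], and central-difference diffusion
#' \eqn{F_{diff} = -D e^{-c}|_{i+1/2} (u_{i+1} - u_i)/dx}. Food depletes
#' locally, \eqn{dc_i/dt = -\kappa c_i \rho_i}. Fluxes telescope around the
#' periodic domain and the kinetics are antisymmetric, so
#' \eqn{\sum_i (ds_i + dg_i) dx = 0} identically.
#'
#' This R implementation is deliberately independent of the compiled fast
#' path used by [simulate_locusts()]; the two are cross-checked in the test
#' suite.
#'
#' @param state a [locust_state()].
#' @param params a [locust_params()].
#' @param grid a [locust_grid()].
#' @param freeze_kinetics,freeze_food logical switches as in
#'   [solver_config()].
#' @param velocity_override optional scalar replacing both advective
#'   velocities (testing hook for pure-advection configurations).
#' @return A list with components `ds`, `dg`, `dc`.
#' @export
locust_rhs <- function(state, params, grid, freeze_kinetics = FALSE,
                       freeze_food = FALSE, velocity_override = NULL) {
  stopifnot(inherits(state, "locust_state"))
  for (nm in c("s", "g", "c")) {
    u <- state[[nm]]
    if (anyNA(u) || any(!is.finite(u)))
      stop("integration failure: non-finite value in field '", nm,
           "' at cell ", which(!is.finite(u))[1], call. = FALSE)
  }
  n <- grid$n
  ip <- c(2:n, 1L)
  im <- c(n, 1:(n - 1))
  dxi <- 1 / grid$dx
  if (is.null(velocity_override)) {
    v <- velocity_fields(state, params, grid)
    v_g <- v$v_g
    v_s <- v$v_s
  } else {
    v_g <- v_s <- rep(velocity_override, n)
  }
  diff_face <- params$D * 0.5 * (exp(-state$c) + exp(-state$c[ip])) * dxi
  flux <- function(u, v) {
    pmax(v, 0) * u + pmin(v, 0) * u[ip] - diff_face * (u[ip] - u)
  }
  Fs <- flux(state$s, v_s)
  Fg <- flux(state$g, v_g)
  ds <- -(Fs - Fs[im]) * dxi
  dg <- -(Fg - Fg[im]) * dxi
  if (!freeze_kinetics) {
    K <- kinetics_term(state$s, state$g, params)
    ds <- ds + K$ds
    dg <- dg + K$dg
  }
  dc <- if (freeze_food) numeric(n) else -params$kappa * state$c * (state$s + state$g)
  list(ds = ds, dg = dg, dc = dc)
}

#' Integrate the locust model
#'
#' Adaptive embedded Runge-Kutta (Dormand-Prince 5(4), compiled) integration
#' of the semi-discrete system from `initial` to `config$t_end`, landing
#' exactly on each requested output time. The advective velocity is
#' recomputed at every stage (no operator splitting). Negative densities are
#' not clipped; a snapshot more negative than `-1e-8` aborts the run so that
#' conservation stays exact and problems surface rather than being masked.
#'
#' @param initial a non-negative [locust_state()] at `t = 0`.
#' @param params a [locust_params()].
#' @param grid a [locust_grid()].
#' @param config a [solver_config()].
#' @param velocity_override optional scalar constant advection velocity
#'   (testing hook; see [locust_rhs()]).
#' @return An object of class `locust_trajectory`: list with `times`,
#'   `snapshots` (list of [locust_state()]), `diagnostics` (data frame with
#'   columns `t`, `mass`, `phi_g`, `g_peak`, `com`, `food_total`), the
#'   `params`, `grid`, `config`, and solver step counts.
#' @export
simulate_locusts <- function(initial, params, grid, config,
                             velocity_override = NULL) {
  stopifnot(inherits(initial, "locust_state"),
            inherits(params, "locust_params"),
            inherits(grid, "locust_grid"),
            inherits(config, "solver_config"))
  if (min(initial$s) < 0 || min(initial$g) < 0 || min(initial$c) < 0)
    stop("initial state must be non-negative", call. = FALSE)
  qg <- kernel_multiplier(social_potential("gregarious", params), grid)
  qs <- kernel_multiplier(social_potential("solitarious", params), grid)
  y0 <- c(initial$s, initial$g, initial$c)
  res <- .integrate_cpp(y0, unclass(params), grid$n, grid$dx, qg, qs,
                        config$output_times, config$rtol, config$atol,
                        if (is.finite(config$max_step)) config$max_step else -1,
                        config$freeze_kinetics, config$freeze_food,
                        velocity_override)
  snaps <- vector("list", length(config$output_times))
  n <- grid$n
  for (i in seq_along(snaps)) {
    row <- res$snapshots[i, ]
    worst <- min(row[seq_len(2 * n)])
    if (worst < -1e-8)
      stop("integration failure: density fell below -1e-8 (min = ",
           format(worst), ") at t = ", config$output_times[i], call. = FALSE)
    snaps[[i]] <- structure(list(t = config$output_times[i],
                                 s = row[1:n],
                                 g = row[(n + 1):(2 * n)],
                                 c = row[(2 * n + 1):(3 * n)]),
                            class = "locust_state")
  }
  diagnostics <- do.call(rbind, lapply(snaps, function(st) {
    M <- total_mass(st, grid)
    data.frame(t = st$t, mass = M,
               phi_g = if (M > 0) sum(st$g) * grid$dx / M else NA_real_,
               g_peak = max(st$g),
               com = if (M > 0) centre_of_mass(st, grid) else NA_real_,
               food_total = sum(st$c) * grid$dx)
  }))
  structure(list(times = config$output_times, snapshots = snaps,
                 diagnostics = diagnostics, params = params, grid = grid,
                 config = config, n_accept = res$n_accept,
                 n_reject = res$n_reject),
            class = "locust_trajectory")
}

#' @export
print.locust_trajectory <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Locust trajectory: %d snapshots on t = [%g, %g], n = %d cells\n",
              nrow(d), min(d$t), max(d$t), x$grid$n))
  cat(sprintf("  mass %.6g (relative drift %.2e)\n", d$mass[1],
              max(abs(d$mass - d$mass[1])) / d$mass[1]))
  cat(sprintf("  final phi_g = %.4g, peak g = %.4g, food left = %.4g\n",
              d$phi_g[nrow(d)], max(d$g_peak), d$food_total[nrow(d)]))
  cat(sprintf("  %d accepted / %d rejected steps\n", x$n_accept, x$n_reject))
  invisible(x)
}

#' @export
summary.locust_trajectory <- function(object, ...) {
  object$diagnostics
}

#' @export
plot.locust_trajectory <- function(x, which = c("fields", "diagnostics"), ...) {
  which <- match.arg(which)
  if (which == "fields") {
    st <- x$snapshots[[length(x$snapshots)]]
    ylim <- range(0, st$s, st$g, st$c)
    graphics::plot(x$grid$x, st$s, type = "l", col = "blue", ylim = ylim,
                   xlab = "x", ylab = "density",
                   main = sprintf("t = %g", st$t), ...)
    graphics::lines(x$grid$x, st$g, col = "red")
    graphics::lines(x$grid$x, st$c, col = "darkgreen")
    graphics::legend("topright", legend = c("solitarious", "gregarious", "food"),
                     col = c("blue", "red", "darkgreen"), lty = 1, bty = "n")
  } else {
    d <- x$diagnostics
    graphics::plot(d$t, d$g_peak, type = "l", xlab = "t", ylab = "peak g", ...)
  }
  invisible(x)
}

#' Write a snapshot or diagnostics to plain-text files
#'
#' `write_snapshot()` writes one state as columnar text (columns `x`, `s`,
#' `g`, `c`) with a header comment carrying the time and a short hash of the
#' parameter set. `write_diagnostics()` writes the trajectory's diagnostic
#' time series as CSV.
#'
#' @param state a [locust_state()].
#' @param grid a [locust_grid()].
#' @param path output file path.
#' @param params optional [locust_params()] for the header hash.
#' @return The path, invisibly.
#' @export
write_snapshot <- function(state, grid, path, params = NULL) {
  hash <- if (is.null(params)) "" else
    sprintf(" params_hash=%08x",
            sum(cumsum(as.integer(charToRaw(paste(unlist(params), collapse = ","))))) %% 0xFFFFFFF)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t=%.15g%s", state$t, hash), con)
  writeLines("x s g c", con)
  utils::write.table(data.frame(x = grid$x, s = state$s, g = state$g,
                                c = state$c),
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param traj a [simulate_locusts()] trajectory.
#' @rdname write_snapshot
#' @export
write_diagnostics <- function(traj, path) {
  utils::write.csv(traj$diagnostics, path, row.names = FALSE)
  invisible(path)
}
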