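#' Initial food patch specification
#'
#' The initial food field is a smoothed step of mass `F_M` centred at `x0`
#' with footprint width `zeta`:
#' \deqn{c(x, 0) = \frac{F_M}{2\zeta}\left[\tanh(\alpha[x - (x_0 - \zeta/2)])
#'   - \tanh(\alpha[x - (x_0 + \zeta/2)])\right].}
#' The width may equivalently be given as the percentage `omega` of the
#' domain, \eqn{\omega = 100\zeta/L}. The control cases are `omega = 0`
#' (no food, `c = 0`) and `omega = 100` (homogeneous food, `c = F_M/L`).
#' On the infinite line the profile integrates exactly to `F_M`; on the
#' periodic domain it does so to high accuracy for footprints up to half the
#' domain.
#'
#' @param F_M total food mass (>= 0).
#' @param omega footprint as a percentage of the domain (0 to 100); give
#'   either this or `zeta`.
#' @param zeta absolute footprint width.
#' @param alpha step steepness (default 7).
#' @param x0 patch centre (default `L/2`, resolved against the grid).
#' @return An object of class `food_ic`.
#' @export
food_ic <- function(F_M, omega = NULL, zeta = NULL, alpha = 7, x0 = NULL) {
  stopifnot(F_M >= 0, alpha > 0)
  if (is.null(omega) == is.null(zeta))
    stop("give exactly one of 'omega' or 'zeta'", call. = FALSE)
  if (!is.null(omega) && (omega < 0 || omega > 100))
    stop("omega must lie in [0, 100]", call. = FALSE)
  if (!is.null(zeta) && zeta < 0)
    stop("zeta must be non-negative", call. = FALSE)
  structure(list(F_M = F_M, omega = omega, zeta = zeta, alpha = alpha,
                 x0 = x0),
            class = "food_ic")
}

#' Initial locust density specification
#'
#' Locusts start all-solitarious at ambient density `rho_amb` with
#' multiplicative cell noise:
#' \deqn{s(x, 0) = \frac{\rho_{amb}}{16.6}(16.6 + \mu), \qquad g(x, 0) = 0,}
#' where \eqn{\mu \sim N(0, 1)} per cell, truncated to \eqn{\pm 4} standard
#' deviations so the density cannot go negative (the noise amplitude is
#' about 6\% of ambient). The noise realisation is a pure function of
#' `seed` (and the cell count), so the same \eqn{\mu} vector is reused
#' across every `rho_amb` for a given seed — replicate initial conditions
#' are rescaled, not redrawn.
#'
#' @param rho_amb ambient total density (> 0).
#' @param seed replicate identifier (integer).
#' @return An object of class `locust_ic`.
#' @export
locust_ic <- function(rho_amb, seed = 1L) {
  stopifnot(rho_amb > 0, length(seed) == 1L)
  structure(list(rho_amb = rho_amb, seed = as.integer(seed)),
            class = "locust_ic")
}

# Draw the frozen noise vector for a seed without disturbing the caller's RNG.
noise_vector <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  pmin(pmax(stats::rnorm(n), -4), 4)
}

#' Assemble an initial model state
#'
#' Evaluates the locust and food initial-condition formulas at the cell
#' centres of `grid` and returns the combined state at `t = 0`.
#'
#' @param locust a [locust_ic()].
#' @param food a [food_ic()].
#' @param grid a [locust_grid()].
#' @return A [locust_state()].
#' @export
make_initial_state <- function(locust, food, grid) {
  stopifnot(inherits(locust, "locust_ic"), inherits(food, "food_ic"),
            inherits(grid, "locust_grid"))
  mu <- noise_vector(grid$n, locust$seed)
  s0 <- locust$rho_amb * (16.6 + mu) / 16.6
  omega <- if (is.null(food$omega)) 100 * food$zeta / grid$L else food$omega
  zeta <- if (is.null(food$zeta)) food$omega * grid$L / 100 else food$zeta
  if (zeta >= grid$L && omega < 100)
    stop("food footprint zeta must be smaller than the domain", call. = FALSE)
  x0 <- if (is.null(food$x0)) grid$L / 2 else food$x0
  c0 <- if (omega == 0 || food$F_M == 0) {
    rep(0, grid$n)
  } else if (omega >= 100) {
    rep(food$F_M / grid$L, grid$n)
  } else {
    a <- food$alpha
    food$F_M / (2 * zeta) *
      (tanh(a * (grid$x - (x0 - zeta / 2))) -
       tanh(a * (grid$x - (x0 + zeta / 2))))
  }
  locust_state(s = s0, g = 0, c = c0, grid = grid, t = 0)
}

#' Per-capita foraging contact and relative advantage
#'
#' Per-capita contact with food for each phase,
#' \deqn{\eta_s = \frac{1}{M}\int \frac{c\,s}{1 - \phi_g} dx, \qquad
#'   \eta_g = \frac{1}{M}\int \frac{c\,g}{\phi_g} dx,}
#' and the instantaneous relative advantage \eqn{b = \eta_g/\eta_s} of being
#' gregarious. `b = 1` whenever the populations are proportional or the food
#' is uniform; `b > 1` means gregarious individuals access more food per
#' capita. Undefined when either phase is absent (\eqn{\phi_g \in \{0, 1\}}).
#'
#' @param state a [locust_state()].
#' @param grid a [locust_grid()].
#' @return A list with components `eta_s`, `eta_g`, `b`.
#' @export
foraging_metrics <- function(state, grid) {
  M <- total_mass(state, grid)
  if (M <= 0) stop("foraging metrics undefined: total mass is zero",
                   call. = FALSE)
  phi <- gregarious_fraction(state, grid)
  if (phi <= 0 || phi >= 1)
    stop("foraging advantage undefined: one phase is absent (phi_g = ",
         format(phi), ")", call. = FALSE)
  eta_s <- sum(state$c * state$s) * grid$dx / (M * (1 - phi))
  eta_g <- sum(state$c * state$g) * grid$dx / (M * phi)
  list(eta_s = eta_s, eta_g = eta_g, b = eta_g / eta_s)
}

#' Foraging-advantage time series of a trajectory
#'
#' Evaluates [foraging_metrics()] at every snapshot where both phases are
#' present (`phi_g > phi_min`, below `1 - phi_min`) and food remains;
#' other snapshots get `NA`.
#'
#' @param traj a [simulate_locusts()] trajectory.
#' @param phi_min smallest gregarious fraction at which the one-sided ratio
#'   is reported (default `1e-6`).
#' @return A data frame with columns `t`, `phi_g`, `b`.
#' @export
advantage_series <- function(traj, phi_min = 1e-6) {
  grid <- traj$grid
  rows <- lapply(traj$snapshots, function(st) {
    M <- total_mass(st, grid)
    phi <- if (M > 0) sum(st$g) * grid$dx / M else NA_real_
    b <- NA_real_
    if (!is.na(phi) && phi > phi_min && phi < 1 - phi_min &&
        sum(st$c) * grid$dx > 0)
      b <- foraging_metrics(st, grid)$b
    data.frame(t = st$t, phi_g = phi, b = b)
  })
  do.call(rbind, rows)
}

#' Classify group formation from a trajectory
#'
#' A run counts as group formation when the peak gregarious density reaches
#' a multiple of the ambient density: `max_t g_peak(t) >= threshold_factor *
#' rho_amb`. The default factor 3 separates homogeneous steady states (peaks
#' below about 1.5 times ambient) from true aggregates (above about 5 times
#' ambient for the packaged parameter sets). With `require_persistence` the
#' criterion must also hold in the final snapshot, which distinguishes
#' transient clumps that dissolve again from persistent groups.
#'
#' @param traj a [simulate_locusts()] trajectory.
#' @param rho_amb the ambient density of the run.
#' @param threshold_factor peak multiple of ambient that counts as a group
#'   (default 3).
#' @param require_persistence also require the criterion at the final time
#'   (default `FALSE`).
#' @return A list with components `formed`, `t_formed` (`NA` when no
#'   crossing) and `peak_g`.
#' @export
classify_formation <- function(traj, rho_amb, threshold_factor = 3,
                               require_persistence = FALSE) {
  d <- traj$diagnostics
  thr <- threshold_factor * rho_amb
  hit <- d$g_peak >= thr
  formed <- any(hit)
  if (require_persistence) formed <- formed && hit[length(hit)]
  list(formed = formed,
       t_formed = if (any(hit)) d$t[which(hit)[1]] else NA_real_,
       peak_g = max(d$g_peak))
}

#' Sweep ambient density, food footprint and food mass
#'
#' Runs the full model over the Cartesian product of `rho_amb`, `omega` and
#' `F_M` for each replicate seed, recording per run the peak gregarious
#' density, the formation classification and the foraging-advantage series.
#' Replicates share their noise realisation across `rho_amb` values (the
#' frozen-noise protocol of [locust_ic()]), so records are deterministic
#' given seeds and independent of execution order. Individual run failures
#' are caught and recorded with `error` set, and the sweep continues.
#'
#' The production design mirrors the model's study conditions: domain
#' `L = 3/0.14`, `t_end = 12.5`, symmetric parameters swept over
#' `rho_amb` in `[0.8, 1.4]`, `F_M` in `{1.5, 2, 2.5, 3}` and asymmetric
#' over `rho_amb` in `[0.3, 0.55]`, `F_M` in `{1.5, 3}`, with footprints
#' from 2.5\% to 50\% plus the `omega = 0` and `omega = 100` controls.
#'
#' @param params a [locust_params()].
#' @param grid a [locust_grid()].
#' @param rho_amb ambient densities to sweep.
#' @param omega food footprints (percent of domain) to sweep.
#' @param F_M food masses to sweep.
#' @param replicates seeds of the replicate noise realisations (default
#'   `1:3`).
#' @param config a [solver_config()] (default `t_end = 12.5`).
#' @param threshold_factor,require_persistence passed to
#'   [classify_formation()].
#' @return An object of class `locust_sweep`: a list of records, each with
#'   `rho_amb`, `omega`, `F_M`, `seed`, `peak_g`, `formed`, `t_formed`,
#'   `phi_g_final`, `advantage` (data frame) and `error` (`NULL` on
#'   success).
#' @seealso [aggregate_sweep()] for the max-over-replicates reduction.
#' @export
run_sweep <- function(params, grid, rho_amb, omega, F_M, replicates = 1:3,
                      config = solver_config(t_end = 12.5),
                      threshold_factor = 3, require_persistence = FALSE) {
  cases <- expand.grid(rho_amb = rho_amb, omega = omega, F_M = F_M,
                       seed = replicates, KEEP.OUT.ATTRS = FALSE)
  records <- lapply(seq_len(nrow(cases)), function(i) {
    cs <- cases[i, ]
    rec <- list(rho_amb = cs$rho_amb, omega = cs$omega, F_M = cs$F_M,
                seed = cs$seed, peak_g = NA_real_, formed = NA,
                t_formed = NA_real_, phi_g_final = NA_real_,
                advantage = NULL, error = NULL)
    tryCatch({
      st0 <- make_initial_state(locust_ic(cs$rho_amb, cs$seed),
                                food_ic(cs$F_M, omega = cs$omega), grid)
      traj <- simulate_locusts(st0, params, grid, config)
      cls <- classify_formation(traj, cs$rho_amb, threshold_factor,
                                require_persistence)
      rec$peak_g <- cls$peak_g
      rec$formed <- cls$formed
      rec$t_formed <- cls$t_formed
      rec$phi_g_final <- traj$diagnostics$phi_g[nrow(traj$diagnostics)]
      rec$advantage <- advantage_series(traj)
      rec
    }, error = function(e) {
      rec$error <- conditionMessage(e)
      rec
    })
  })
  structure(records, class = "locust_sweep")
}

#' @export
print.locust_sweep <- function(x, ...) {
  cat(sprintf("Locust sweep: %d runs (%d failed)\n", length(x),
              sum(vapply(x, function(r) !is.null(r$error), logical(1)))))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' @export
as.data.frame.locust_sweep <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(rho_amb = r$rho_amb, omega = r$omega, F_M = r$F_M,
               seed = r$seed, peak_g = r$peak_g, formed = r$formed,
               t_formed = r$t_formed, phi_g_final = r$phi_g_final,
               failed = !is.null(r$error))
  }))
}

#' Reduce sweep replicates by maximum peak density
#'
#' Collapses replicate runs of each `(rho_amb, omega, F_M)` combination to
#' the replicate with the largest peak gregarious density — the reduction
#' used to draw formation phase diagrams. A combination counts as formed if
#' any replicate formed.
#'
#' @param sweep a [run_sweep()] result.
#' @return A data frame with one row per combination.
#' @export
aggregate_sweep <- function(sweep) {
  df <- as.data.frame(sweep)
  df <- df[!df$failed, ]
  key <- interaction(df$rho_amb, df$omega, df$F_M, drop = TRUE)
  rows <- lapply(split(df, key), function(grp) {
    best <- grp[which.max(grp$peak_g), ]
    best$formed <- any(grp$formed)
    best$seed <- NULL
    best
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$rho_amb, out$omega, out$F_M), ]
}
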