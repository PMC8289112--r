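#' Model state on a grid
#'
#' Bundles the three cell-averaged fields at one time point: solitarious
#' density `s`, gregarious density `g` and food density `c`. Scalars are
#' recycled to uniform fields. Densities may dip marginally below zero
#' (down to `-1e-10`) to tolerate solver round-off; anything more negative
#' is rejected.
#'
#' @param s,g,c density fields (length `n` or scalar).
#' @param grid a [locust_grid()].
#' @param t time stamp (default 0).
#' @return An object of class `locust_state` with fields `t`, `s`, `g`, `c`.
#' @export
locust_state <- function(s, g, c, grid, t = 0) {
  stopifnot(inherits(grid, "locust_grid"))
  s <- as_grid_field(s, grid, "s")
  g <- as_grid_field(g, grid, "g")
  c <- as_grid_field(c, grid, "c")
  for (nm in c("s", "g", "c")) {
    u <- get(nm)
    if (min(u) < -1e-10)
      stop("field '", nm, "' is negative beyond solver tolerance (min = ",
           format(min(u)), ")", call. = FALSE)
  }
  structure(list(t = t, s = s, g = g, c = c), class = "locust_state")
}

#' @export
print.locust_state <- function(x, ...) {
  cat(sprintf("Locust state at t = %g (%d cells)\n", x$t, length(x$s)))
  cat(sprintf("  s: [%.4g, %.4g]  g: [%.4g, %.4g]  c: [%.4g, %.4g]\n",
              min(x$s), max(x$s), min(x$g), max(x$g), min(x$c), max(x$c)))
  invisible(x)
}

#' Total locust mass
#'
#' Midpoint-rule mass \eqn{M = \sum_i (s_i + g_i)\,dx} of the combined
#' solitarious and gregarious populations.
#'
#' @param state a [locust_state()].
#' @param grid the [locust_grid()] the state lives on.
#' @return A scalar mass.
#' @export
total_mass <- function(state, grid) {
  stopifnot(inherits(state, "locust_state"), inherits(grid, "locust_grid"))
  sum(state$s + state$g) * grid$dx
}

#' Global gregarious mass fraction
#'
#' The fraction \eqn{\phi_g = \int g\,dx / M} of total locust mass in the
#' gregarious state. Group formation requires this fraction to exceed a
#' food- and density-dependent threshold (see [phi_threshold()]).
#'
#' @inheritParams total_mass
#' @return A scalar in \eqn{[0, 1]}.
#' @export
gregarious_fraction <- function(state, grid) {
  M <- total_mass(state, grid)
  if (M <= 0)
    stop("gregarious fraction undefined: total mass is zero", call. = FALSE)
  sum(state$g) * grid$dx / M
}

#' Circular centre of mass
#'
#' Mass-weighted mean position of the total density on the periodic domain,
#' computed via the circular mean of cell angles
#' \eqn{\theta_i = 2\pi x_i / L}. With a spatially uniform, constant food
#' field the model preserves this quantity up to discretisation error.
#'
#' @inheritParams total_mass
#' @return A position in \eqn{[0, L)}.
#' @export
centre_of_mass <- function(state, grid) {
  stopifnot(inherits(state, "locust_state"), inherits(grid, "locust_grid"))
  rho <- state$s + state$g
  if (sum(rho) <= 0)
    stop("centre of mass undefined: total mass is zero", call. = FALSE)
  theta <- 2 * pi * grid$x / grid$L
  ang <- atan2(sum(rho * sin(theta)), sum(rho * cos(theta)))
  (grid$L * ang / (2 * pi)) %% grid$L
}
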