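#' Social interaction potentials
#'
#' The nonlocal fluxes of the model derive from exponential social potentials:
#' solitarious locusts feel pure repulsion
#' \eqn{Q_s(x) = R_s e^{-|x|/r_s}}, while gregarious locusts feel short-range
#' repulsion plus longer-range attraction
#' \eqn{Q_g(x) = R_g e^{-|x|/r_g} - A_g e^{-|x|}} (the attraction range is 1
#' in dimensionless variables). `social_potential()` captures the relevant
#' constants from a parameter set.
#'
#' @param kind `"solitarious"` or `"gregarious"`.
#' @param params a [locust_params()] object.
#' @return An object of class `social_potential`.
#' @export
social_potential <- function(kind = c("solitarious", "gregarious"), params) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "locust_params"))
  spec <- if (kind == "solitarious") {
    list(kind = kind, R = params$R_s, r = params$r_s)
  } else {
    list(kind = kind, R = params$R_g, r = params$r_g, A = params$A_g)
  }
  structure(spec, class = "social_potential")
}

#' Evaluate a social potential pointwise
#'
#' @param spec a [social_potential()].
#' @param x positions (vectorised).
#' @return Potential values \eqn{Q(x)}.
#' @export
potential_value <- function(spec, x) {
  stopifnot(inherits(spec, "social_potential"))
  v <- spec$R * exp(-abs(x) / spec$r)
  if (spec$kind == "gregarious") v <- v - spec$A * exp(-abs(x))
  v
}

#' Fourier transform of a social potential
#'
#' Closed-form continuum transforms under the convention
#' \eqn{\hat f(\kappa) = \int f(x) e^{-i\kappa x} dx}:
#' \eqn{\hat Q_s(\kappa) = 2 R_s r_s / (1 + r_s^2 \kappa^2)} and
#' \eqn{\hat Q_g(\kappa) = 2 R_g r_g / (1 + r_g^2\kappa^2) - 2 A_g/(1 + \kappa^2)}.
#' Both are real and even. \eqn{\hat Q_g(0) < 0} exactly when long-range
#' attraction outweighs repulsion (`A_g > R_g * r_g`).
#'
#' @param spec a [social_potential()].
#' @param kappa wavenumbers (vectorised).
#' @return Transform values \eqn{\hat Q(\kappa)}.
#' @export
potential_hat <- function(spec, kappa) {
  stopifnot(inherits(spec, "social_potential"))
  v <- 2 * spec$R * spec$r / (1 + spec$r^2 * kappa^2)
  if (spec$kind == "gregarious") v <- v - 2 * spec$A / (1 + kappa^2)
  v
}

#' Spectral multiplier of a social potential on a grid
#'
#' The diagonal factor applied in Fourier space by [convolve_periodic()].
#' Two representations are available. `"sampled"` (the default) is the DFT of
#' the periodised kernel \eqn{\sum_p Q(x + pL)} sampled at the grid offsets,
#' scaled by `dx`; with it the spectral convolution reproduces the direct
#' wrapped Riemann sum \eqn{\sum_j Q_{wrap}(x_i - x_j) u_j\, dx} to machine
#' precision, so the scheme is verifiable against plain summation.
#' `"continuum"` uses the closed-form transform [potential_hat()] at the grid
#' wavenumbers, which treats the field as its trigonometric interpolant and
#' avoids sampling the kink of \eqn{e^{-|x|/r}} at the origin. The two differ
#' by the \eqn{O(dx^2)} quadrature error of the kink; both converge to the
#' continuum periodic convolution.
#'
#' @param spec a [social_potential()].
#' @param grid a [locust_grid()].
#' @param transform `"sampled"` or `"continuum"`.
#' @return A real vector of length `n` in FFT storage order.
#' @export
kernel_multiplier <- function(spec, grid,
                              transform = c("sampled", "continuum")) {
  stopifnot(inherits(spec, "social_potential"), inherits(grid, "locust_grid"))
  transform <- match.arg(transform)
  if (transform == "continuum") return(potential_hat(spec, grid$kappa))
  offsets <- (seq_len(grid$n) - 1) * grid$dx
  p_max <- max(5, ceiling(40 * max(spec$r, 1) / grid$L))
  K <- numeric(grid$n)
  for (p in -p_max:p_max)
    K <- K + potential_value(spec, offsets + p * grid$L)
  Re(fft(K)) * grid$dx
}

#' Periodic convolution with a social potential
#'
#' Computes \eqn{(Q \star u)(x_i)} at the cell centres spectrally: discrete
#' Fourier transform of the field, multiplication by the kernel's spectral
#' multiplier at the grid wavenumbers \eqn{\kappa_m = 2\pi m / L}
#' (see [kernel_multiplier()]), inverse transform. The default `"sampled"`
#' multiplier makes the result identical (to round-off) to the brute-force
#' sum over the wrapped kernel \eqn{\sum_p Q(x + pL)}. A warning is emitted
#' when a kernel range reaches `L/8`, where periodic wrap-around materially
#' distorts the interaction.
#'
#' @param field density values per cell.
#' @param spec a [social_potential()].
#' @param grid a [locust_grid()].
#' @param transform multiplier representation, see [kernel_multiplier()].
#' @return The convolved field at cell centres (real vector).
#' @export
convolve_periodic <- function(field, spec, grid,
                              transform = c("sampled", "continuum")) {
  stopifnot(inherits(spec, "social_potential"), inherits(grid, "locust_grid"))
  field <- as_grid_field(field, grid, "field")
  ranges <- c(spec$r, if (spec$kind == "gregarious") 1)
  if (any(ranges >= grid$L / 8))
    warning("kernel range >= L/8: periodic wrap-around distorts the kernel",
            call. = FALSE)
  qhat <- kernel_multiplier(spec, grid, transform)
  out <- fft(qhat * fft(field), inverse = TRUE) / grid$n
  re <- Re(out)
  scale <- max(abs(re), 1e-300)
  if (max(abs(Im(out))) > 1e-12 * max(scale, 1))
    warning("convolution has unexpectedly large imaginary part", call. = FALSE)
  re
}

#' Advective velocity fields at cell interfaces
#'
#' Assembles the dimensionless advection velocities
#' \deqn{v_g = -\partial_x(Q_g \star \rho) + D e^{-c}(\partial_x c -
#'   \gamma \rho \partial_x \rho)}
#' (and analogously \eqn{v_s} with \eqn{Q_s}) at the `n` cell interfaces
#' \eqn{x_{i+1/2}}, with periodic wrap. Gradients of cell-centred fields use
#' the two adjacent cells, \eqn{(u_{i+1} - u_i)/dx}; interface values of
#' \eqn{e^{-c}} and \eqn{\rho} are arithmetic means of the adjacent cells.
#' Element `i` of each returned vector is the velocity at the interface
#' between cells `i` and `i + 1` (interface `n` wraps to cell 1).
#'
#' @param state a [locust_state()].
#' @param params a [locust_params()].
#' @param grid a [locust_grid()].
#' @return A list with components `v_g` and `v_s`, each of length `n`.
#' @export
velocity_fields <- function(state, params, grid) {
  stopifnot(inherits(state, "locust_state"), inherits(params, "locust_params"))
  rho <- state$s + state$g
  Pg <- convolve_periodic(rho, social_potential("gregarious", params), grid)
  Ps <- convolve_periodic(rho, social_potential("solitarious", params), grid)
  ip <- c(2:grid$n, 1L)
  dxi <- 1 / grid$dx
  ec_face <- 0.5 * (exp(-state$c) + exp(-state$c[ip]))
  rho_face <- 0.5 * (rho + rho[ip])
  dc <- (state$c[ip] - state$c) * dxi
  drho <- (rho[ip] - rho) * dxi
  local_part <- params$D * ec_face * (dc - params$gamma * rho_face * drho)
  list(v_g = -(Pg[ip] - Pg) * dxi + local_part,
       v_s = -(Ps[ip] - Ps) * dxi + local_part)
}
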