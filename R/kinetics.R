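#' Density-dependent phase-transition rates
#'
#' `f1()` is the solitarisation rate \eqn{f_1(\rho) = \delta/(1+\rho^2)}
#' (monotone decreasing: crowded locusts rarely revert) and `f2()` the
#' gregarisation rate, either \eqn{(\rho/k)^2/(1+(\rho/k)^2)} (`"divide"`
#' form, the default) or \eqn{(k\rho)^2/(1+(k\rho)^2)} (`"multiply"` form),
#' monotone increasing and saturating at 1. Densities are clipped at zero
#' from below to tolerate solver round-off down to `-1e-10`; genuinely
#' negative densities are a domain error.
#'
#' @param rho total local density (vectorised, >= 0 up to round-off).
#' @param params a [locust_params()].
#' @return Rate values.
#' @export
f1 <- function(rho, params) {
  stopifnot(inherits(params, "locust_params"))
  rho <- clip_density(rho)
  params$delta / (1 + rho^2)
}

#' @rdname f1
#' @export
f2 <- function(rho, params) {
  stopifnot(inherits(params, "locust_params"))
  rho <- clip_density(rho)
  z <- if (params$transition_form == "divide") rho / params$k else params$k * rho
  z^2 / (1 + z^2)
}

clip_density <- function(rho) {
  if (any(rho < -1e-10))
    stop("negative density beyond solver tolerance in transition rate",
         call. = FALSE)
  pmax(rho, 0)
}

#' Phase-transition reaction terms
#'
#' The kinetics exchange mass between the phases without creating or
#' destroying it: \eqn{dg/dt = -f_1(\rho) g + f_2(\rho) s} and
#' \eqn{ds/dt = +f_1(\rho) g - f_2(\rho) s}, so the two components sum to
#' zero exactly.
#'
#' @param s,g solitarious and gregarious densities (vectorised).
#' @param params a [locust_params()].
#' @return A list with components `dg` and `ds`.
#' @export
kinetics_term <- function(s, g, params) {
  rho <- s + g
  dg <- -f1(rho, params) * g + f2(rho, params) * s
  list(dg = dg, ds = -dg)
}

#' Steady-state gregarious fraction of a homogeneous population
#'
#' At uniform density \eqn{\bar\rho} the phase kinetics relax to the
#' gregarious mass fraction
#' \eqn{\phi_{ss} = f_2(\bar\rho) / (f_1(\bar\rho) + f_2(\bar\rho))},
#' monotone increasing in \eqn{\bar\rho} for both transition forms.
#'
#' @param rho_bar homogeneous total density (>= 0; returns 0 at 0).
#' @param params a [locust_params()].
#' @return A fraction in \eqn{[0, 1)}.
#' @export
steady_fraction <- function(rho_bar, params) {
  a <- f1(rho_bar, params)
  b <- f2(rho_bar, params)
  ifelse(rho_bar == 0, 0, b / (a + b))
}

#' Homogeneous gregarisation dynamics
#'
#' With space ignored, total density \eqn{\bar\rho} fixed and \eqn{g(0) = 0},
#' the gregarious density follows the closed form
#' \deqn{g(t) = \bar\rho\,\frac{f_2}{f_1 + f_2}
#'   \left(1 - e^{-(f_1 + f_2)t}\right),}
#' rising monotonically to \eqn{\bar\rho\,\phi_{ss}}. Inverting this curve at
#' the instability threshold gives the time-to-formation estimate
#' ([time_to_formation()]).
#'
#' @param t time (vectorised, >= 0).
#' @param rho_bar homogeneous total density.
#' @param params a [locust_params()].
#' @return Gregarious density at time `t`.
#' @export
homogeneous_g <- function(t, rho_bar, params) {
  stopifnot(all(t >= 0))
  a <- f1(rho_bar, params)
  b <- f2(rho_bar, params)
  rho_bar * (b / (a + b)) * (1 - exp(-(a + b) * t))
}
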