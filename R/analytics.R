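#' Gradient-flow energy of a pure gregarious population
#'
#' With constant food, no solitarious locusts and phase transitions switched
#' off, the gregarious equation is a gradient flow of
#' \deqn{E[g] = \int \tfrac12 g (Q_g \star g) + \frac{D e^{-c}\gamma}{6} g^3
#'   + D e^{-c} (g \log g - g)\, dx,}
#' so the energy is non-increasing along trajectories. The entropy term uses
#' the convention \eqn{0 \log 0 = 0}. Quadrature is the midpoint sum; the
#' convolution is spectral.
#'
#' @param g gregarious density field (>= 0 up to `-1e-10` round-off).
#' @param c_bar constant food level.
#' @param params a [locust_params()].
#' @param grid a [locust_grid()].
#' @return A scalar energy.
#' @export
aggregation_energy <- function(g, c_bar, params, grid) {
  stopifnot(inherits(params, "locust_params"), inherits(grid, "locust_grid"))
  g <- as_grid_field(g, grid, "g")
  if (min(g) < -1e-10)
    stop("g is negative beyond solver tolerance", call. = FALSE)
  g <- pmax(g, 0)
  conv <- convolve_periodic(g, social_potential("gregarious", params), grid)
  dec <- params$D * exp(-c_bar)
  entropy <- ifelse(g > 0, g * log(g) - g, 0)
  sum(0.5 * g * conv + dec * params$gamma * g^3 / 6 + dec * entropy) * grid$dx
}

check_attraction <- function(params) {
  if (params$A_g <= params$R_g * params$r_g)
    stop("no aggregation: requires net long-range attraction (A_g > R_g * r_g)",
         call. = FALSE)
}

new_mass_limit <- function(regime, g_max, support, M, c_bar, params) {
  structure(list(regime = regime, g_max = g_max, support = support,
                 M = M, c_bar = c_bar, params = params),
            class = "mass_limit_estimate")
}

#' @export
print.mass_limit_estimate <- function(x, ...) {
  cat(sprintf("%s-mass aggregate estimate (M = %g, c = %g):\n",
              x$regime, x$M, x$c_bar))
  cat(sprintf("  max density ||g||_inf = %.6g, support |Omega| = %.6g\n",
              x$g_max, x$support))
  invisible(x)
}

#' Large-mass limit of the gregarious aggregate
#'
#' For a large population the aggregate profile is approximately rectangular
#' and the short-range parts of the potential act as contact interactions,
#' giving the mass-independent maximum density
#' \deqn{\|g\|_\infty = \frac{3\left[(A_g - R_g r_g) +
#'   \sqrt{(R_g r_g - A_g)^2 - \tfrac43 (D e^{-\bar c})^2 \gamma}\right]}
#'   {2 D e^{-\bar c} \gamma}}
#' and support \eqn{\|\Omega\| = M / \|g\|_\infty} (the direct closed form
#' for the support is algebraically identical; a single code path avoids
#' divergence under round-off). Food raises the maximum density through the
#' \eqn{e^{-\bar c}} factors.
#'
#' @param M total mass (> 0).
#' @param c_bar constant food level.
#' @param params a [locust_params()]; requires `A_g > R_g * r_g`.
#' @return A `mass_limit_estimate` with `regime = "large"`.
#' @export
large_mass_limit <- function(M, c_bar, params) {
  stopifnot(inherits(params, "locust_params"), M > 0)
  check_attraction(params)
  dec <- params$D * exp(-c_bar)
  net <- params$A_g - params$R_g * params$r_g
  disc <- net^2 - 4 * dec^2 * params$gamma / 3
  if (disc < 0)
    stop("no aggregation: diffusion dominates attraction (negative discriminant)",
         call. = FALSE)
  g_max <- 3 * (net + sqrt(disc)) / (2 * dec * params$gamma)
  new_mass_limit("large", g_max, M / g_max, M, c_bar, params)
}

#' Small-mass limit of the gregarious aggregate
#'
#' For a small population the potential is Taylor-expanded about the origin
#' and linear diffusion neglected inside the aggregate, giving
#' \deqn{\|g\|_\infty = \left[\frac{3 M^2 (A_g - R_g r_g)}
#'   {4 D e^{-\bar c} \gamma}\right]^{1/3}, \qquad
#'   \|\Omega\| = B\!\left(\tfrac23, \tfrac12\right)
#'   \left[\frac{M D e^{-\bar c} \gamma}{6 (A_g - R_g r_g)}\right]^{1/3},}
#' where \eqn{B} is the Euler beta function. The maximum density scales as
#' \eqn{M^{2/3}}; this regime is less accurate than the large-mass one but
#' shows the same qualitative effect of food.
#'
#' @inheritParams large_mass_limit
#' @return A `mass_limit_estimate` with `regime = "small"`.
#' @export
small_mass_limit <- function(M, c_bar, params) {
  stopifnot(inherits(params, "locust_params"), M > 0)
  check_attraction(params)
  dec <- params$D * exp(-c_bar)
  net <- params$A_g - params$R_g * params$r_g
  g_max <- (3 * M^2 * net / (4 * dec * params$gamma))^(1 / 3)
  support <- beta(2 / 3, 1 / 2) * (M * dec * params$gamma / (6 * net))^(1 / 3)
  new_mass_limit("small", g_max, support, M, c_bar, params)
}

#' Gregarious-fraction threshold for group formation
#'
#' Linear stability of the homogeneous steady state \eqn{(\bar s, \bar g,
#' \bar c)} with non-depleting food: a perturbation at wavenumber
#' \eqn{\kappa} grows exactly when the gregarious mass fraction exceeds
#' \deqn{\bar\phi_g(\kappa) = \frac{D e^{-\bar c}/\bar\rho +
#'   D e^{-\bar c}\bar\rho\gamma + \hat Q_s(\kappa)}
#'   {\hat Q_s(\kappa) - \hat Q_g(\kappa)}.}
#' The default `kappa = 0` long-wave mode gives the closed form with
#' \eqn{\hat Q_s(0) = 2 R_s r_s} and
#' \eqn{\hat Q_s(0) - \hat Q_g(0) = 2A_g - 2R_g r_g + 2R_s r_s}. On a finite
#' periodic domain only modes \eqn{\kappa_m \ge 2\pi/L} are admissible, so a
#' finite `kappa` evaluation is provided for domain-aware predictions. The
#' threshold may exceed 1 (formation impossible at any fraction) and is
#' `Inf` when the denominator is non-positive (stable at all fractions).
#' More food (larger \eqn{\bar c}) strictly lowers the threshold.
#'
#' @param rho_bar homogeneous total density (> 0).
#' @param c_bar homogeneous food level.
#' @param params a [locust_params()].
#' @param kappa wavenumber of the perturbation mode (default 0, the
#'   long-wave limit).
#' @return The threshold fraction (possibly `Inf`).
#' @export
phi_threshold <- function(rho_bar, c_bar, params, kappa = 0) {
  stopifnot(inherits(params, "locust_params"), rho_bar > 0)
  qs <- potential_hat(social_potential("solitarious", params), kappa)
  qg <- potential_hat(social_potential("gregarious", params), kappa)
  denom <- qs - qg
  dec <- params$D * exp(-c_bar)
  num <- dec / rho_bar + dec * rho_bar * params$gamma + qs
  ifelse(denom <= 0, Inf, num / denom)
}

#' Upper density bound for group formation
#'
#' Setting the threshold fraction to 1 and solving for \eqn{\bar\rho} gives
#' the largest homogeneous density at which instability is possible:
#' \deqn{\bar\rho_{max} = \frac{(A_g - R_g r_g) +
#'   \sqrt{(A_g - R_g r_g)^2 - (D e^{-\bar c})^2\gamma}}{D e^{-\bar c}\gamma},}
#' approaching \eqn{\tfrac23 \|g\|_\infty} of the large-mass limit when
#' \eqn{(D e^{-\bar c})^2 \gamma \ll (A_g - R_g r_g)^2}. Beyond this density
#' the environment is too thick with locusts for aggregations to form.
#'
#' @inheritParams phi_threshold
#' @return The bounding density.
#' @export
rho_upper_bound <- function(c_bar, params) {
  stopifnot(inherits(params, "locust_params"))
  dec <- params$D * exp(-c_bar)
  net <- params$A_g - params$R_g * params$r_g
  disc <- net^2 - dec^2 * params$gamma
  if (disc < 0)
    stop("no instability window: diffusion dominates at every density",
         call. = FALSE)
  (net + sqrt(disc)) / (dec * params$gamma)
}

#' Time until a homogeneous population can form groups
#'
#' The homogeneous gregarisation curve [homogeneous_g()] crosses the
#' instability threshold \eqn{\bar\phi_g \bar\rho} at
#' \deqn{t^* = \frac{-\ln\!\left(1 - \bar\phi_g (f_1 + f_2)/f_2\right)}
#'   {f_1 + f_2},}
#' the exact inversion of the closed-form solution. Returns `Inf` when the
#' trajectory never crosses (i.e. \eqn{\bar\phi_g (f_1+f_2)/f_2 \ge 1}),
#' and 0 when the threshold is already met at \eqn{g = 0}.
#'
#' @inheritParams phi_threshold
#' @return A non-negative time, possibly `Inf`.
#' @export
time_to_formation <- function(rho_bar, c_bar, params) {
  stopifnot(rho_bar > 0)
  phibar <- phi_threshold(rho_bar, c_bar, params, kappa = 0)
  a <- f1(rho_bar, params)
  b <- f2(rho_bar, params)
  arg <- 1 - phibar * (a + b) / b
  if (!is.finite(phibar) || arg <= 0) return(Inf)
  -log(arg) / (a + b)
}

#' Can a homogeneous density destabilise into a group?
#'
#' Combines the kinetic steady state with the stability threshold: groups can
#' form from a uniform population at density \eqn{\bar\rho} exactly when
#' \deqn{\frac{f_2(\bar\rho)}{f_1(\bar\rho) + f_2(\bar\rho)} > \bar\phi_g.}
#' The report also carries the upper density bound (when defined) and the
#' time-to-formation estimate, which is finite precisely when the condition
#' holds.
#'
#' @inheritParams phi_threshold
#' @return An object of class `stability_report` with fields `rho_bar`,
#'   `c_bar`, `phi_threshold`, `phi_ss`, `forms`, `rho_upper` (`NA` if no
#'   instability window exists) and `t_star`.
#' @export
formation_condition <- function(rho_bar, c_bar, params) {
  phibar <- phi_threshold(rho_bar, c_bar, params, kappa = 0)
  phiss <- steady_fraction(rho_bar, params)
  rho_up <- tryCatch(rho_upper_bound(c_bar, params), error = function(e) NA_real_)
  structure(list(rho_bar = rho_bar, c_bar = c_bar,
                 phi_threshold = phibar, phi_ss = phiss,
                 forms = phiss > phibar,
                 rho_upper = rho_up,
                 t_star = time_to_formation(rho_bar, c_bar, params)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Homogeneous state rho = %g, c = %g:\n", x$rho_bar, x$c_bar))
  cat(sprintf("  threshold fraction  %.5g\n", x$phi_threshold))
  cat(sprintf("  steady fraction     %.5g\n", x$phi_ss))
  cat(sprintf("  group formation     %s\n",
              if (x$forms) "possible" else "not possible"))
  if (is.finite(x$t_star))
    cat(sprintf("  time to formation   %.5g\n", x$t_star))
  if (!is.na(x$rho_upper))
    cat(sprintf("  upper density bound %.5g\n", x$rho_upper))
  invisible(x)
}

#' Tabulate the formation condition over density/food ranges
#'
#' Evaluates [formation_condition()] on the Cartesian product of the supplied
#' densities and food levels; convenient for mapping the phase boundary.
#'
#' @param rho_bar vector of homogeneous densities.
#' @param c_bar vector of homogeneous food levels.
#' @param params a [locust_params()].
#' @return A data frame with columns `rho_bar`, `c_bar`, `phi_threshold`,
#'   `phi_ss`, `forms`, `t_star`.
#' @export
stability_table <- function(rho_bar, c_bar, params) {
  cases <- expand.grid(rho_bar = rho_bar, c_bar = c_bar,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    r <- formation_condition(cases$rho_bar[i], cases$c_bar[i], params)
    data.frame(rho_bar = r$rho_bar, c_bar = r$c_bar,
               phi_threshold = r$phi_threshold, phi_ss = r$phi_ss,
               forms = r$forms, t_star = r$t_star)
  })
  do.call(rbind, rows)
}
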