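#' Dimensionless model parameters
#'
#' Constructs the set of dimensionless constants governing the
#' solitarious/gregarious locust continuum model: linear diffusion `D`,
#' nonlinear local repulsion `gamma`, the exponential social-potential
#' strengths and ranges (`R_s`, `r_s` for solitarious repulsion; `R_g`, `r_g`,
#' `A_g` for gregarious repulsion/attraction, the attraction range being 1
#' after nondimensionalisation), the phase-transition constants `k` (ratio of
#' half-maximal transition densities) and `delta` (ratio of maximal transition
#' rates), and the food consumption rate `kappa`.
#'
#' `transition_form` selects the reading of the gregarisation rate
#' \eqn{f_2}: `"divide"` gives \eqn{(\rho/k)^2/(1+(\rho/k)^2)}, `"multiply"`
#' gives \eqn{(k\rho)^2/(1+(k\rho)^2)}. The default is `"divide"`, matching
#' the dimensional form \eqn{\delta_2 (\rho/k_2)^2/(1+(\rho/k_2)^2)}; the
#' alternative is exposed because the two readings place the no-food
#' instability boundary at different ambient densities (see the methods
#' vignette).
#'
#' Biologically the model expects short-range gregarious repulsion and
#' longer-range attraction (`r_g < 1`, `r_s >= r_g`); violations produce a
#' warning, not an error. `A_g > R_g * r_g` (net long-range attraction) is
#' required by the mass-limit formulas and is checked where those are invoked.
#'
#' @param D linear diffusion coefficient (> 0).
#' @param gamma nonlinear (local repulsion) diffusion coefficient (> 0).
#' @param R_s,r_s solitarious repulsion strength and range (> 0).
#' @param R_g,r_g gregarious repulsion strength and range (> 0).
#' @param A_g gregarious attraction strength (> 0); attraction range is 1.
#' @param k ratio of half-maximal transition densities (> 0).
#' @param delta ratio of maximal phase-transition rates (> 0).
#' @param kappa food consumption rate (>= 0).
#' @param transition_form `"divide"` or `"multiply"` (see Details).
#' @return An object of class `locust_params`.
#' @seealso [preset_params()] for the two packaged parameter sets,
#'   [nondimensionalise()] to derive one from dimensional inputs.
#' @examples
#' p <- preset_params("symmetric")
#' p$gamma
#' @export
locust_params <- function(D, gamma, R_s, r_s, R_g, r_g, A_g, k, delta, kappa,
                          transition_form = c("divide", "multiply")) {
  transition_form <- match.arg(transition_form)
  num <- list(D = D, gamma = gamma, R_s = R_s, r_s = r_s, R_g = R_g,
              r_g = r_g, A_g = A_g, k = k, delta = delta, kappa = kappa)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  strict_pos <- setdiff(names(num), "kappa")
  bad <- strict_pos[vapply(num[strict_pos], function(v) v <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (kappa < 0) stop("kappa must be non-negative", call. = FALSE)
  if (r_g >= 1)
    warning("r_g >= 1: gregarious repulsion is not shorter-ranged than attraction",
            call. = FALSE)
  if (r_s < r_g)
    warning("r_s < r_g: solitarious repulsion range below gregarious repulsion range",
            call. = FALSE)
  structure(c(num, list(transition_form = transition_form)),
            class = "locust_params")
}

#' Packaged dimensionless parameter sets
#'
#' Two calibrations of the model distinguished by the relative time frames of
#' gregarisation and solitarisation. In the `"symmetric"` set (`delta = 1`,
#' `k = 0.681`) the two transitions take equal time, characteristic of the
#' desert locust. In the `"asymmetric"` set (`delta = 1.778`, `k = 0.1`)
#' solitarisation is much slower than gregarisation, as reported for the
#' Australian plague locust. The same values ship as plain-text configuration
#' files under `inst/extdata` (see [read_params()]).
#'
#' @param name `"symmetric"` or `"asymmetric"`.
#' @param transition_form passed on to [locust_params()].
#' @return A `locust_params` object.
#' @export
preset_params <- function(name = c("symmetric", "asymmetric"),
                          transition_form = c("divide", "multiply")) {
  name <- match.arg(name)
  transition_form <- match.arg(transition_form)
  switch(name,
    symmetric = locust_params(
      D = 2.041, gamma = 431.87, R_s = 1063.5, r_s = 1, R_g = 940.5,
      r_g = 0.2857, A_g = 2008.7, k = 0.681, delta = 1, kappa = 0.09,
      transition_form = transition_form),
    asymmetric = locust_params(
      D = 2.041, gamma = 294.44, R_s = 878.1, r_s = 1, R_g = 775.6,
      r_g = 0.2857, A_g = 1658.6, k = 0.1, delta = 1.778, kappa = 0.18,
      transition_form = transition_form))
}

#' @export
print.locust_params <- function(x, ...) {
  cat("Dimensionless locust model parameters\n")
  cat(sprintf("  diffusion        D = %g, gamma = %g\n", x$D, x$gamma))
  cat(sprintf("  solitarious      R_s = %g, r_s = %g\n", x$R_s, x$r_s))
  cat(sprintf("  gregarious       R_g = %g, r_g = %g, A_g = %g\n",
              x$R_g, x$r_g, x$A_g))
  cat(sprintf("  kinetics         k = %g, delta = %g (f2 form: %s)\n",
              x$k, x$delta, x$transition_form))
  cat(sprintf("  food consumption kappa = %g\n", x$kappa))
  invisible(x)
}

#' Dimensional model parameters
#'
#' Container for the dimensional counterparts of the model constants, used by
#' [nondimensionalise()]. Units are the user's (consistent) choice of time,
#' length and density; the model never manipulates units itself.
#'
#' @param delta1,delta2 maximal solitarisation/gregarisation rates (1/time).
#' @param k1,k2 half-maximal transition densities (locusts/length).
#' @param a_g gregarious attraction sensing distance (length).
#' @param c0 feeding-stationarity food scale (mass/area).
#' @param D_dim,gamma_dim,kappa_dim dimensional diffusion, local-repulsion and
#'   consumption coefficients.
#' @param Rs_dim,rs_dim,Rg_dim,rg_dim,Ag_dim dimensional social-potential
#'   strengths and ranges.
#' @return An object of class `dimensional_params`.
#' @export
dimensional_params <- function(delta1, delta2, k1, k2, a_g, c0,
                               D_dim, gamma_dim, kappa_dim,
                               Rs_dim, rs_dim, Rg_dim, rg_dim, Ag_dim) {
  vals <- list(delta1 = delta1, delta2 = delta2, k1 = k1, k2 = k2, a_g = a_g,
               c0 = c0, D_dim = D_dim, gamma_dim = gamma_dim,
               kappa_dim = kappa_dim, Rs_dim = Rs_dim, rs_dim = rs_dim,
               Rg_dim = Rg_dim, rg_dim = rg_dim, Ag_dim = Ag_dim)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("dimensional parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(vals, class = "dimensional_params")
}

#' Nondimensionalise a dimensional parameter set
#'
#' Applies the model's scalings (time by `1/delta2`, space by the attraction
#' range `a_g`, densities by `k1`, food by `c0`) to produce the dimensionless
#' parameter set:
#' \deqn{D = D_{dim}/(\delta_2 a_g^2),\quad \gamma = k_1^2\gamma_{dim},\quad
#'   \delta = \delta_1/\delta_2,\quad k = k_1/k_2,\quad
#'   \kappa = \kappa_{dim} k_1/\delta_2,}
#' with each nonlocal strength mapped by \eqn{X \mapsto X k_1/(\delta_2 a_g)}
#' and ranges by \eqn{r \mapsto r/a_g}.
#'
#' @param dim a [dimensional_params()] object.
#' @param transition_form passed on to [locust_params()].
#' @return A `locust_params` object.
#' @seealso [redimensionalise()] for the inverse map.
#' @export
nondimensionalise <- function(dim, transition_form = c("divide", "multiply")) {
  if (!inherits(dim, "dimensional_params"))
    stop("'dim' must be a dimensional_params object", call. = FALSE)
  locust_params(
    D = dim$D_dim / (dim$delta2 * dim$a_g^2),
    gamma = dim$k1^2 * dim$gamma_dim,
    R_s = dim$Rs_dim * dim$k1 / (dim$delta2 * dim$a_g),
    r_s = dim$rs_dim / dim$a_g,
    R_g = dim$Rg_dim * dim$k1 / (dim$delta2 * dim$a_g),
    r_g = dim$rg_dim / dim$a_g,
    A_g = dim$Ag_dim * dim$k1 / (dim$delta2 * dim$a_g),
    k = dim$k1 / dim$k2,
    delta = dim$delta1 / dim$delta2,
    kappa = dim$kappa_dim * dim$k1 / dim$delta2,
    transition_form = transition_form)
}

#' Recover dimensional parameters from a dimensionless set
#'
#' Inverse of [nondimensionalise()]: given the reference scales `delta2`
#' (gregarisation rate), `a_g` (attraction range), `k1` (density scale) and
#' `c0` (food scale), reconstructs the dimensional parameter set.
#'
#' @param params a `locust_params` object.
#' @param delta2,a_g,k1,c0 the positive reference scales.
#' @return A `dimensional_params` object.
#' @export
redimensionalise <- function(params, delta2, a_g, k1, c0) {
  stopifnot(inherits(params, "locust_params"),
            delta2 > 0, a_g > 0, k1 > 0, c0 > 0)
  dimensional_params(
    delta1 = params$delta * delta2,
    delta2 = delta2,
    k1 = k1,
    k2 = k1 / params$k,
    a_g = a_g,
    c0 = c0,
    D_dim = params$D * delta2 * a_g^2,
    gamma_dim = params$gamma / k1^2,
    kappa_dim = params$kappa * delta2 / k1,
    Rs_dim = params$R_s * delta2 * a_g / k1,
    rs_dim = params$r_s * a_g,
    Rg_dim = params$R_g * delta2 * a_g / k1,
    rg_dim = params$r_g * a_g,
    Ag_dim = params$A_g * delta2 * a_g / k1)
}

#' Read or write parameter configuration files
#'
#' Parameter files are flat key/value YAML with the field names of
#' [locust_params()]. Two presets ship with the package:
#' `system.file("extdata", "params-symmetric.yaml", package = "locustform")`
#' and the analogous `params-asymmetric.yaml`.
#'
#' @param path file path.
#' @return `read_params()` returns a `locust_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- c("D", "gamma", "R_s", "r_s", "R_g", "r_g", "A_g", "k", "delta",
             "kappa", "transition_form")
  extra <- setdiff(names(vals), known)
  if (length(extra))
    warning("ignoring unknown parameter keys: ", paste(extra, collapse = ", "),
            call. = FALSE)
  do.call(locust_params, vals[intersect(known, names(vals))])
}

#' @param params a `locust_params` object to serialise.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "locust_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
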