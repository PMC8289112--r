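#' Periodic one-dimensional finite-volume grid
#'
#' Cell-centred mesh on the half-open periodic interval \eqn{[0, L)} with `n`
#' equal cells of width `dx = L/n` and centres \eqn{x_i = (i + 1/2)dx}. All
#' integrals over states on the grid are midpoint sums. The grid also carries
#' the discrete wavenumbers \eqn{\kappa_m = 2\pi m/L} in FFT storage order,
#' used for spectral convolution with the social potentials.
#'
#' @param L domain length (dimensionless; the production experiments use
#'   `L = 3/0.14`).
#' @param n number of cells (at least 8).
#' @return An object of class `locust_grid` with fields `L`, `n`, `dx`, cell
#'   centres `x`, and wavenumbers `kappa`.
#' @examples
#' gr <- locust_grid(L = 3 / 0.14, n = 128)
#' gr$dx * gr$n == gr$L
#' @export
locust_grid <- function(L, n) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("L must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 8)
    stop("n must be an integer >= 8", call. = FALSE)
  n <- as.integer(n)
  dx <- L / n
  h <- n %/% 2L
  m <- c(0:h, seq_len(n - h - 1L) - (n - h))  # FFT order: 0..h, -(n-h-1)..-1
  structure(list(L = L, n = n, dx = dx,
                 x = (seq_len(n) - 0.5) * dx,
                 kappa = 2 * pi * m / L),
            class = "locust_grid")
}

#' @export
print.locust_grid <- function(x, ...) {
  cat(sprintf("Periodic 1-D grid: L = %g, n = %d cells, dx = %g\n",
              x$L, x$n, x$dx))
  invisible(x)
}

as_grid_field <- function(u, grid, name) {
  u <- as.numeric(u)
  if (length(u) == 1L) u <- rep(u, grid$n)
  if (length(u) != grid$n)
    stop("field '", name, "' must have length 1 or n = ", grid$n,
         call. = FALSE)
  if (anyNA(u) || any(!is.finite(u)))
    stop("field '", name, "' contains non-finite values", call. = FALSE)
  u
}
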