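# Shared fixtures: parameter sets and small grids used across the suite.

sym_params <- function(...) preset_params("symmetric", ...)
asym_params <- function(...) preset_params("asymmetric", ...)

# Gentle parameter set with O(1) potentials and weak diffusion, used wherever
# the packaged presets' stiffness would make a test needlessly slow.
mild_params <- function(kappa = 0.09) {
  suppressWarnings(locust_params(
    D = 0.01, gamma = 60, R_s = 0.25, r_s = 1, R_g = 0.25, r_g = 0.5,
    A_g = 1, k = 0.681, delta = 1, kappa = kappa))
}

# Brute-force periodic convolution: direct O(n^2) sum over the wrapped kernel
# Q_wrap(x) = sum_p Q(x + pL), |p| <= 5. Independent oracle for the spectral
# path.
wrapped_kernel_value <- function(spec, x, L, p_max = 5) {
  v <- 0
  for (p in -p_max:p_max) v <- v + potential_value(spec, x + p * L)
  v
}

brute_convolve <- function(field, spec, grid, p_max = 5) {
  n <- grid$n
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- sum(wrapped_kernel_value(spec, grid$x[i] - grid$x, grid$L,
                                       p_max) * field) * grid$dx
  }
  out
}

# Uniform state helper
uniform_state <- function(s, g, c, grid) locust_state(s, g, c, grid)
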