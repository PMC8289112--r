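---
title: "Modelling locust group formation under heterogeneous food"
author: "locustform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling locust group formation under heterogeneous food}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locustform)
```

## The model

Locusts exhibit density-dependent phase polyphenism: solitarious individuals
avoid conspecifics, gregarious individuals seek them out, and the two states
interconvert at density-dependent rates. `locustform` implements a
one-dimensional continuum model of this process on a periodic domain. The
state is three fields: solitarious density $s(x,t)$, gregarious density
$g(x,t)$ and food density $c(x,t)$, with total density $\rho = s + g$. In
dimensionless variables the governing equations are

$$
\partial_t g + \partial_x(g\,v_g) - D\,\partial_x\!\left(e^{-c}\partial_x g\right)
  = -f_1(\rho)\,g + f_2(\rho)\,s,
$$
$$
\partial_t s + \partial_x(s\,v_s) - D\,\partial_x\!\left(e^{-c}\partial_x s\right)
  = +f_1(\rho)\,g - f_2(\rho)\,s,
$$
$$
\partial_t c = -\kappa\, c\,\rho,
$$

with advection velocities

$$
v_{g} = -\partial_x(Q_g \star \rho) + D e^{-c}\left(\partial_x c
  - \gamma\,\rho\,\partial_x \rho\right),
\qquad
v_{s} = -\partial_x(Q_s \star \rho) + D e^{-c}\left(\partial_x c
  - \gamma\,\rho\,\partial_x \rho\right).
$$

The three transport mechanisms are: nonlocal social interactions through the
exponential potentials
$Q_s(x) = R_s e^{-|x|/r_s}$ (repulsion only) and
$Q_g(x) = R_g e^{-|x|/r_g} - A_g e^{-|x|}$ (short-range repulsion, longer
range attraction; the attraction range is scaled to 1); local crowd
repulsion through the nonlinear-diffusion velocity term with coefficient
$\gamma$; and food interactions — locusts slow down on food (every local
flux carries the factor $e^{-c}$) and drift up food gradients. Food is
consumed by mass action at rate $\kappa$ and is not replenished on the
group-formation time scale. Phase switching uses

$$
f_1(\rho) = \frac{\delta}{1+\rho^2}, \qquad
f_2(\rho) = \frac{(\rho/k)^2}{1+(\rho/k)^2},
$$

so crowding suppresses solitarisation and promotes gregarisation. Locust
mass is conserved exactly (births and deaths are ignored), and with
spatially uniform constant food the first moment of $\rho$ is conserved too.

## Parameters

Two packaged presets (`preset_params()`) represent distinct gregarisation
biologies; all values are dimensionless.

| parameter | symmetric | asymmetric | meaning |
|---|---|---|---|
| $D$ | 2.041 | 2.041 | linear diffusion |
| $\gamma$ | 431.87 | 294.44 | local (crowd) repulsion |
| $R_s, r_s$ | 1063.5, 1 | 878.1, 1 | solitarious repulsion strength, range |
| $R_g, r_g$ | 940.5, 0.2857 | 775.6, 0.2857 | gregarious repulsion strength, range |
| $A_g$ | 2008.7 | 1658.6 | gregarious attraction strength |
| $k$ | 0.681 | 0.1 | ratio of half-maximal transition densities |
| $\delta$ | 1 | 1.778 | ratio of maximal transition rates |
| $\kappa$ | 0.09 | 0.18 | food consumption rate |

In the symmetric set gregarisation and solitarisation take equal time
(desert-locust-like); in the asymmetric set solitarisation is an order of
magnitude slower (plague-locust-like). `nondimensionalise()` maps a
dimensional parameter file onto this set (time scaled by the maximal
gregarisation rate, space by the attraction range, density by the
half-maximal gregarisation density); `redimensionalise()` inverts it.

**The $f_2$ reading.** The rendered sources are typographically ambiguous
between $f_2 = (\rho/k)^2/(1+(\rho/k)^2)$ and $(k\rho)^2/(1+(k\rho)^2)$.
We default to the *divide* form, which matches the printed dimensional
expression $f_2(\rho) = \delta_2 (\rho/k_2)^2/(1+(\rho/k_2)^2)$, and expose
`transition_form = "multiply"` because the two readings place the no-food
instability boundary of the symmetric set at different ambient densities
(near $\bar\rho \approx 0.9$ for divide, between 1.4 and 1.5 for multiply),
and neither reading reproduces every qualitative statement made about the
asymmetric set. `stability_table()` makes it easy to map the boundary under
either reading.

## Closed-form analytics

With constant uniform food, a pure gregarious population is a gradient flow
of the energy

$$
E[g] = \int \tfrac12 g (Q_g\!\star\!g)
 + \frac{De^{-c}\gamma}{6} g^3 + De^{-c}(g\log g - g)\,dx ,
$$

(`aggregation_energy()`), which the solver must not increase — this is one
of the sharpest integration tests available for the scheme. Approximating
the minimiser yields the aggregate profiles:

* **Large mass** (`large_mass_limit()`): rectangular profile with
  mass-independent maximum density; the short-range kernel parts act as
  contact interactions ($e^{-|x|/r} \approx 2r\,\delta(x)$).
* **Small mass** (`small_mass_limit()`): Taylor-expanded kernel and no
  linear diffusion, giving $\|g\|_\infty \propto M^{2/3}$ and a beta-function
  support formula.

Both are *estimates* with quantifiable error. Their assumptions fail in
measurable ways at moderate mass: the delta-kernel step requires the support
to be much wider than the attraction range (at $M = 20$ with the
weak-interaction parameter set used for validation the support is only a few
attraction ranges, and an independent minimisation of $E$ — mirror descent
on the discrete energy, agreeing with the PDE solver to four digits — sits
about 20% below the rectangle estimate), and the dropped entropy term
$De^{-c}\log g$ is *not* negligible at small mass (at $M = 0.1$ it lowers
the true peak roughly threefold). The package therefore tests the
*convergence trend* — the simulated peak approaches the large-mass formula
as $M$ grows — rather than pretending pointwise agreement at moderate mass;
the acceptance checks report the measured ratios.

Linear stability of the homogeneous state $(\bar s,\bar g,\bar c)$ with
$\kappa = 0$ gives the threshold gregarious fraction for group formation
(`phi_threshold()`):

$$
\bar\phi_g(\kappa) =
\frac{De^{-\bar c}/\bar\rho + De^{-\bar c}\bar\rho\gamma + \hat Q_s(\kappa)}
     {\hat Q_s(\kappa) - \hat Q_g(\kappa)},
$$

where the total-density perturbation mode $\tilde\rho \propto e^{i\kappa x}$
closes on itself with growth rate
$-\kappa^2[De^{-\bar c}(1 + \gamma\bar\rho^2)
+ \bar\rho(\phi\hat Q_g + (1-\phi)\hat Q_s)]$ — positive exactly when
$\phi > \bar\phi_g(\kappa)$. The $\kappa = 0$ long-wave form is the default;
on a finite periodic domain the smallest admissible wavenumber is
$2\pi/L$, and passing `kappa` explicitly gives the domain-aware prediction.
Derived from it are the upper density bound for group formation
(`rho_upper_bound()`, the density at which the threshold reaches 1), the
implicit formation condition $\phi_{ss} > \bar\phi_g$ combining kinetic
steady state and threshold (`formation_condition()`), and the
time-to-formation estimate (`time_to_formation()`), the exact inversion of
the homogeneous gregarisation curve
$g(t) = \bar\rho\,\phi_{ss}(1 - e^{-(f_1+f_2)t})$. More food lowers both
the threshold and the formation time; these monotonicities are tested as
properties.

## Numerical scheme

The solver is a conservative method of lines on a cell-centred periodic
finite-volume grid (`locust_grid()`; production runs use $L = 3/0.14$,
$n = 512$ by default, $n = 128$–256 in tests and desk-scale sweeps):

* **Advection**: first-order upwind interface fluxes
  $F_{i+1/2} = v^+ u_i + v^- u_{i+1}$, with the velocity assembled at
  interfaces from two-point gradients. Interface values of $e^{-c}$ and
  $\rho$ are arithmetic means of the adjacent cells (the coefficients are
  smooth and positive; harmonic averaging offers nothing here, and one
  convention is used for both the advective and diffusive coefficient).
* **Diffusion**: central differences with the same interface coefficient.
* **Nonlocal terms**: spectral convolution. The multiplier applied in
  Fourier space is, by default, the DFT of the periodised kernel sampled at
  the grid offsets (`kernel_multiplier(..., "sampled")`), which makes the
  spectral product *identical to machine precision* with the direct wrapped
  sum $\sum_j Q_{wrap}(x_i - x_j)u_j\,dx$ — so the FFT path is verifiable
  against brute-force summation. The alternative `"continuum"` multiplier
  evaluates the closed-form transforms
  $\hat Q_s = 2R_sr_s/(1+r_s^2\kappa^2)$,
  $\hat Q_g = 2R_gr_g/(1+r_g^2\kappa^2) - 2A_g/(1+\kappa^2)$ at the grid
  wavenumbers, which is exact for the trigonometric interpolant of the
  field and avoids sampling the $|x|$ kink. The two differ only by the
  $O(dx^2)$ kink-quadrature error (about $10^{-3}$ relative at $n = 64$ on
  the domains used here) and converge to the same continuum operator.
* **Time stepping**: an embedded Dormand–Prince 5(4) pair with standard
  error control (`rtol = 1e-6`, `atol = 1e-9` defaults), implemented in
  compiled code together with the right-hand side. The velocity is
  recomputed at every stage — no operator splitting — so the gradient-flow
  energy test sees the genuine semi-discrete flow. Because the advective
  fluxes telescope around the ring and the kinetics are antisymmetric,
  total locust mass is a *linear invariant* of the semi-discrete system and
  every Runge–Kutta step conserves it to round-off (measured drift
  $\sim 10^{-15}$ relative over the full production horizon).
* **Positivity**: upwinding plus donor-form kinetics keep densities
  non-negative at the stable step size; negative round-off is tolerated to
  $-10^{-8}$ and *never clipped* — clipping would silently break
  conservation, so a violation fails the run instead.
* **Stiffness**: the explicit stable step is set by the nonlinear-diffusion
  coefficient $De^{-c}\gamma\rho^2$; with the packaged presets and $n = 256$
  this is $O(10^{-6})$ time units, which is why the right-hand side and
  integrator are compiled and allocation-free (an R-level reference
  implementation, `locust_rhs()`, is kept and cross-checked against the
  compiled path and against an independent adaptive integrator in the test
  suite).

A deliberately small R surface mirrors each piece (`velocity_fields()`,
`convolve_periodic()`, `locust_rhs()`) so every stage of the scheme can be
unit-tested against independent oracles: quadrature for the kernel
transforms, $O(n^2)$ wrapped sums for convolution and energy, closed forms
for homogeneous kinetics and food decay, and method-of-characteristics for
pure advection.

## Synthetic experiments

The experiment layer generates exactly the study conditions of the model's
numerical experiments; it is first-class, tested code.

* **Locust initial condition** (`locust_ic()`):
  $s(x,0) = \rho_{amb}(16.6 + \mu)/16.6$, $g(x,0) = 0$, with $\mu \sim N(0,1)$
  per cell. The constant 16.6 sets the noise amplitude at about 6% of
  ambient. $\mu$ is truncated at $\pm 4$ standard deviations (by clamping —
  deterministic, with bias $\sim 3\times10^{-5}$ per cell) so the density
  cannot start negative. The noise vector is a pure function of the seed,
  so replicate initial conditions are *rescaled* across ambient densities,
  never redrawn — sweeps are comparable across $\rho_{amb}$ by
  construction.
* **Food initial condition** (`food_ic()`): a smoothed step of mass $F_M$,
  width $\zeta$ (equivalently $\omega = 100\zeta/L$ percent of the domain),
  steepness $\alpha = 7$, centred at $L/2$; $\omega = 0$ and $\omega = 100$
  are the no-food and homogeneous-food controls.
* **Sweeps** (`run_sweep()`): Cartesian product of $\rho_{amb}$, $\omega$,
  $F_M$ and replicate seeds with the max-over-replicates reduction
  (`aggregate_sweep()`). Production ranges: symmetric
  $\rho_{amb} \in [0.8, 1.4]$, $F_M \in \{1.5, 2, 2.5, 3\}$; asymmetric
  $\rho_{amb} \in [0.3, 0.55]$, $F_M \in \{1.5, 3\}$; footprints 2.5–50%
  plus controls; $t_{end} = 12.5$.
* **Formation classification** (`classify_formation()`): the sources
  classify formation visually from peak gregarious density; we use
  `peak >= 3 * rho_amb`, since homogeneous steady states peak below about
  $1.5\rho_{amb}$ while true aggregates exceed $5\rho_{amb}$ for both
  presets, leaving a wide indifferent band around the factor 3. An optional
  persistence requirement (criterion must also hold at $t_{end}$) separates
  transient clumps that dissolve from persistent groups.
* **Foraging metrics** (`foraging_metrics()`): per-capita food contact
  $\eta_s, \eta_g$ and the instantaneous relative advantage
  $b = \eta_g/\eta_s$; $b = 1$ exactly for proportional populations or
  uniform food. In a *depleting* uniform-food control the initial density
  noise imprints slightly on $c$ before diffusion smooths it, so $b$
  deviates from 1 at $O(10^{-5})$ — a property of the model, not an error;
  the non-depleting control holds $b = 1$ to solver precision.

What the generator does *not* emulate: real vegetation patchiness (a single
centred patch only), locust age structure or hunger state, alignment and
collective-motion mechanics of marching bands, and any two-dimensional
effect. Passing tests therefore validate the model's internal consistency
and its closed-form analysis — not field realism.

## Numerical choices and degenerate inputs

* Grids need $n \ge 8$; kernels wider than $L/8$ trigger a wrap-around
  warning.
* Transition rates clip densities at 0 from below (tolerating $-10^{-10}$
  of solver round-off) and refuse anything more negative.
* `phi_threshold()` returns `Inf` when the denominator
  $\hat Q_s - \hat Q_g$ is non-positive (stable at all fractions);
  `time_to_formation()` returns `Inf` when the homogeneous trajectory never
  crosses the threshold; `rho_upper_bound()` and the mass limits raise
  errors when their discriminants indicate diffusion dominates attraction.
* The large-mass support is reported as $M/\|g\|_\infty$, algebraically
  identical to the printed support formula but immune to round-off
  amplification near the discriminant root.
* Zero total mass makes the gregarious fraction, centre of mass and
  foraging metrics undefined — these error rather than return NaN.
* The homogeneous-dynamics and stability tests integrate on deliberately
  coarse grids ($n = 16$–256) where the explicit stable step is large;
  problem sizes in the test suite ($n \le 512$, horizons $\le 12.5$) were
  chosen so the whole suite, including two full-horizon production-preset
  conservation runs, completes in minutes while still exercising every
  regime the analysis covers.

## Known limitations

* First-order upwinding smears sharp aggregate edges over several cells;
  the observed $L^1$ self-convergence order under grid doubling is about 1.
* The explicit integrator makes very dense aggregates (peak $g \gtrsim 6$
  with the production presets) expensive; an IMEX treatment of the
  nonlinear diffusion would lift this but is out of scope.
* The circular centre of mass (well-defined on the torus) differs from the
  conserved linear first moment by a term that depends on the distribution
  shape; the conservation diagnostic is meaningful when the mass is compact
  and away from the periodic seam.
* The mass-limit formulas are asymptotic estimates; see above for their
  measured accuracy at moderate mass.
* No existence/uniqueness machinery and no two-dimensional solver.
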