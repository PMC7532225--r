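---
title: "Three-phase-lag bio-heat conduction: model, solution and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-phase-lag bio-heat conduction: model, solution and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tplheat)
```

## The model

Heat transport in perfused living tissue is classically described by the
Pennes equation: Fourier conduction plus a volumetric sink
$\omega_b \rho_b c_b (T_a - T)$ that models arterial blood entering at core
temperature $T_a$ and equilibrating locally, plus metabolic and external
volumetric sources.  Fourier conduction propagates disturbances at infinite
speed; in strongly non-homogeneous media such as skin a finite propagation
speed is observed, which motivates constitutive laws in which the heat flux
lags its driving gradients.  The family implemented here is, in increasing
generality:

* **Pennes** — flux proportional to the instantaneous temperature gradient;
* **C-V (thermal wave)** — a flux relaxation time $\tau_q$ gives the
  telegraph equation and the finite wave speed
  $V = \sqrt{k/(\tau_q \rho_t c_t)}$;
* **DPL** — a second lag $\tau_T$ on the temperature gradient restores a
  diffusive (parabolic) character while retaining lagging;
* **TPL** — a third constitutive variable, the thermal displacement $v$
  with $\dot v = T$, enters through its gradient with rate of thermal
  conductivity $k^*$ (W/(m·K·s)) and its own lag $\tau_v$.

Expanding the three-phase-lag flux law to first order in the lags,
eliminating the flux through an energy balance written for the combined
variable $T + (k^*/k)v$, and passing to the increment
$\theta = T - T_a$, one obtains a single third-order-in-time equation on
the slab $0 \le x \le L$:

$$
a_3\,\theta_{ttt} + b_3\,\theta_{tt} + c_3\,\theta_t
 + \omega_b \rho_b c_b \tfrac{k^*}{k}\,\theta
 = \left[k\tau_T\,\partial_{tt} + (k + k^*\tau_v)\,\partial_t + k^*\right]
   \theta_{xx},
$$

with $a_3 = \tau_q \rho_t c_t$,
$b_3 = \rho_t c_t k_q + \tau_q\,\omega_b \rho_b c_b$,
$c_3 = \rho_t c_t k^*/k + \omega_b \rho_b c_b k_q$ and
$k_q = 1 + \tau_q k^*/k$, starting from rest
($\theta = \theta_t = \theta_{tt} = 0$).  Setting $k^* = 0$ and
integrating once in time recovers the DPL equation; additionally
$\tau_T = \tau_v = 0$ gives C-V, and $\tau_q = 0$ Pennes.
`reduce_model()` performs exactly these reductions on a parameter set, and
`validate_params()` enforces the labels' consistency.

Two surface loads are supported, both switched on as a step at $t = 0$
while the inner face stays at arterial temperature
($\theta(L, t) = 0$): a prescribed surface temperature
$\theta(0,t) = \theta_0 H(t)$ (case I), and a prescribed laser flux
$\partial_x\theta(0,t) = Q_0(1 - R_d)H(t)$ (case II), with $Q_0$ the
irradiance and $R_d$ the diffuse reflectance.

### The flux-case sign convention

The case II boundary condition above is dimensionally inconsistent as a
physical Fourier condition (it equates W/m² to K/m) and has the sign of a
*cooling* surface under positive irradiance; it is nevertheless the form
the solution family is conventionally written in, so it is the default
(`flux_convention = "as_printed"`).  The Fourier-consistent alternative
$\partial_x\theta(0,t) = -Q_0(1-R_d)/k$ is available as
`flux_convention = "physical"`.  The package deliberately does not
"correct" the default: reproducing the printed solution family is the
point, and the discrepancy is surfaced here and in the documentation
instead.

## Solution by eigenfunction expansion

The boundary load is homogenised through the steady profile
$\varphi(x)$, which solves $\varphi'' = \lambda^2 \varphi$ with
$\lambda = \sqrt{\omega_b \rho_b c_b / k}$ and the case boundary values
(`steady_profile()`; the $\omega_b = 0$ limits are taken analytically).
Writing $\theta = \theta_1 + \varphi(x)H(t)$, the transient part has
homogeneous boundary conditions and expands in the sine modes
$\lambda_n = n\pi/L$ (case I) or cosine modes
$\lambda_n = (2n-1)\pi/(2L)$ (case II).  Each modal amplitude satisfies

$$
a B_n''' + b B_n'' + c B_n' + d B_n = f_n(t),
$$

with coefficients given by `cubic_coefficients()`.  The characteristic
cubic is classified by the Cardano invariants $p$, $q$ and discriminant
$\Delta = (q/2)^2 + (p/3)^3$ into four root configurations, and the
corresponding initial-value kernels $V_0, V_1, V_2$ (responses to unit
initial value, slope and curvature) are evaluated in closed form
(`classify_cubic()`, `kernel_functions()`).

### How the step load enters the modes

Substituting the decomposition into the governing equation leaves, on the
right-hand side of the modal equation, distributional forcing
proportional to derivatives of the Heaviside function:
$f_n = -c_n\,[a\,\delta'' + b_2\,\delta' + c_2\,\delta]$, where
$c_n = (2/L)\int_0^L Y_n \varphi\,dx$ is the eigenbasis projection of the
steady profile (closed form in `projection_coefficient()`) and
$b_2 = \rho_t c_t k_q + \omega_b\rho_b c_b(\tau_q - \tau_T)$,
$c_2 = (\rho_t c_t + \omega_b\rho_b c_b(\tau_q - \tau_v))k^*/k$ are the
bracket coefficients that survive after the steady terms cancel.  Solving
the modal equation *from rest through this forcing* (a three-line Laplace
computation) gives

$$
B_n(t) = -c_n\left[V_2''(t) + \tfrac{b_2}{a}V_2'(t)
         + \tfrac{c_2}{a}V_2(t)\right].
$$

This reading was a genuine design decision.  The tempting alternative —
absorb the step into "initial conditions" $B_n(0) = -c_n$ with zero
derivatives and no forcing, i.e. $B_n = -c_n V_0(t)$ — looks equivalent
but is not: for every $k^* = 0$ reduction the cubic has $d = 0$, a zero
root, and then $V_0 \equiv 1$, so that reading freezes the field at zero
for all time.  The distributional solution also satisfies
$\theta(x,0)=0$ (since $V_2''(0) = 1$), reduces *exactly* to the
telegraph-equation solution for C-V and to the diffusion solution for
Pennes, and is the one the finite-difference oracle confirms across all
variants (the oracle knows nothing of the modal algebra: it integrates
the PDE from rest with the boundary step).  A unit test additionally
integrates the modal ODE under a narrow smooth ramp replacing the step
and recovers the same histories.

For $\tau_q = 0$ the leading coefficient vanishes and the mode equation
drops order; the Pennes path uses the first-order solution
$B_n = -c_n e^{-\mu_n t}$ with
$\mu_n = (\omega_b\rho_b c_b + k\lambda_n^2)/(\rho_t c_t)$ directly.
The remaining $\tau_q = 0$ combinations ($k^* > 0$ or $\tau_T > 0$) are
outside the supported family and are rejected with an error rather than
approximated.

The field is then
$\theta(x,t) = \sum_{n\le N} Y_n(x)B_n(t) + \varphi(x)H(t)$
(`temperature_field()`).  The steady part is always evaluated in closed
form, never through its own eigenexpansion — this removes the stationary
Gibbs error of the boundary discontinuity and leaves only the transient
part truncated.

## Numerical design choices

**Truncation.**  The default $N = 300$ is the reference choice: at the
midpoint probe the $N=300$ and $N=400$ histories differ by well under
0.5 % of the load scale (`convergence_report()` tabulates this).  At
$t = 0$ the series equals the truncation residual of $-\varphi$, which is
$O(\theta_0)$ within $\sim L/N$ of the heated face and below 1 % of
$\theta_0$ at interior probes.

**Cardano classification tolerances.**  Floating-point $\Delta$ is never
exactly zero, and $p$, $q$, $\Delta$ computed from rounded coefficients
carry cancellation noise well above machine epsilon relative to their
formulas' term magnitudes.  The degenerate cases are therefore entered
through noise-aware bands: explicit rounding floors for $p$ and $q$ are
propagated into a floor for $\Delta$, with a $10^{-12}$ relative band on
top.  Every closed-form root is polished by one Newton step on the
original cubic.

**Near-coincident roots.**  The distinct-root kernel formulas divide by
root differences and lose roughly $\varepsilon/\mathrm{gap}^2$ digits of
accuracy; at a gap of $10^{-7}$ this already destroys six significant
figures.  When a real pair is closer than $10^{-3}\max(1, |r|)$ the pair
is evaluated through its merged form — the two exponentials combined
analytically via $\sinh(\delta t)/\delta$ — which is exact for every gap
and coincides with the printed double-root formulas at $\delta = 0$.  The
complex-pair kernels are already written in this stable form
(sines over $\beta$), and need no special handling.

**Wavefront detection.**  `wavefront_arrival()` reports the time at which
the probe temperature departs from zero, operationalised as a crossing of
1 % of the load scale with linear interpolation between samples.  The
truncated series *rings ahead of a sharp front*: transient threshold
exceedances appear a few seconds before the C-V front and vanish as $N$
grows.  The default detector therefore uses the last upward crossing
(after which the magnitude stays above threshold), which converges to the
front passage time $x/V$ with increasing $N$; the literal first crossing
is available as `rule = "first"`.

**Oscillation measure.**  The zero-$\tau_v$ wave oscillation near the
heated surface manifests, at the reference parameters, as a rise-and-fall
*below* the steady value rather than an excursion above it.  The package
quantifies non-monotonicity as the largest subsequent drop of the
history; 1 % of the load scale separates the oscillating
($\tau_v = 0$: 5.8 % at $x = 0.05L$) and smooth ($\tau_v = 2$ s: 0.03 %)
regimes cleanly.

## The verification oracle

`oracle_solve()` is an independent numerical solution of the governing
equation, used to verify the series (criterion: agreement to a few per
cent of the load scale over the full space-time grid).  Two schemes:

* **Stiff method of lines** for the smooth/parabolic variants (TPL, DPL,
  Pennes): second-order central Laplacians acting on $\theta$,
  $\dot\theta$, $\ddot\theta$ with weights $k^*$, $k + k^*\tau_v$,
  $k\tau_T$; the physically appropriate time order per variant (3/2/1);
  banded-Jacobian `lsode` with rtol $10^{-6}$, atol $10^{-9}$.  The step
  boundary is smoothed over a 0.02 s quintic ramp so the integrator's
  error control remains meaningful; the ramp's imprint decays within the
  first seconds and is excluded from front-band comparisons.
* **Characteristics transport** for the undamped-front structure
  ($\tau_T = 0$, $k^* = 0$, $\tau_q > 0$): any central scheme rings at
  $O(1)$ amplitude around the moving discontinuity, so the telegraph
  system is advected exactly along characteristics at unit CFL
  ($\Delta t = \Delta x/V$), with the perfusion/relaxation damping
  applied by Strang splitting through the exact matrix exponential of the
  local $2\times 2$ source system.  The front stays one cell sharp; the
  scheme is refined ninefold internally and subsampled exactly onto the
  output grid.  The surface step enters as a one-step impulse on the
  incoming characteristic (case I) or a step in the incoming gradient
  variable (case II).

`agreement_report()` compares two fields, excluding a two-cell spacetime
band along the predicted front trajectory $|x - Vt| \le 2\Delta x$ where
pointwise comparison is ill-posed.

## Problem sizes used by the test suite

The shipped tests run the series at $N = 300$ (400 for the convergence
check) against oracles with 399 spatial cells on a $400 \times 100$
space-time comparison grid over 100 s for all four variants and both load
cases; kernel correctness is checked on 100 randomly generated stable
cubics spanning all four root configurations against high-accuracy ODE
integration; steady-state recovery is probed at 20 interior collocation
points at $t = 600$ s.  These sizes reproduce the study conditions of the
reference analysis; none of them is a tuning knob.

## What the defaults represent — and what they do not

The default parameter set (`bioheat_params()`) is a dermis-scale slab:
$\rho_t = 1190$ kg/m³, $c_t = 3600$ J/(kg·K), $k = 0.235$ W/(m·K),
$\rho_b = 1060$, $c_b = 3770$, $\omega_b = 1.87\times10^{-3}$ 1/s,
$T_a = 37$ °C, $L = 9$ mm, $T_0 = 80$ °C, and lags
$\tau_q = 16$ s, $\tau_T = 6$ s, $\tau_v = 2$ s.  The rate of thermal
conductivity $k^* = 0.1$ W/(m·K·s) deserves a flag: no measurement of
$k^*$ for living tissue exists, and the default is an assumed value
chosen for solution stability and its size relative to $k$ — results
that depend sensitively on $k^*$ should be read as model exploration,
not prediction.  Similarly $\tau_v = 2$ s is set by the stability
ordering $0 \le \tau_v < \tau_T < \tau_q$ rather than by experiment
(`validate_params()` warns, but does not stop, when a fully-positive lag
triple violates the ordering, since e.g. $\tau_v = 0$ is itself a
legitimate study case).

The model family is one-dimensional, single-layer, with
temperature-independent properties, and treats the volumetric sources
$Q_m$, $Q_{laser}$ as zero by default: because the governing equation
differentiates the sources in time, constant sources act only
distributionally at $t = 0$ and do not perturb the transient path.  A
convolution path for *smooth, time-varying* modal forcings exists
(`mode_amplitude(..., forcing=)`), but the physical interpretation of the
differentiated-source term is left open and no default exercises it.
Thermal damage (Arrhenius) integrals, multi-layer geometry and
thermo-elastic coupling are out of scope.

## Known limitations

* **Ripple beside an undamped front.**  For the C-V reduction under a
  step surface temperature, the truncated series oscillates on both sides
  of the moving discontinuity.  The ripple amplitude decays like
  $1/(N\cdot\mathrm{distance})$: at $N = 300$ it is still several per
  cent of $\theta_0$ a few grid cells from the front while the front jump
  is near full amplitude, so pointwise agreement with the oracle at the
  2 % level is achieved everywhere *except* a neighbourhood of the front
  somewhat wider than the two-cell band the comparison excludes.  The
  package reports this honestly rather than smoothing the series; away
  from the front, and for every other variant, agreement is at the few
  tenths of a per cent level.
* **Degenerate lag combinations.**  $\tau_q = 0$ together with
  $k^* > 0$ or $\tau_T > 0$ makes the mode equation implicit in the
  highest derivative and is rejected.
* **Near-triple root clusters** (an isolated root within $\sim10^{-5}$ of
  a complex pair) are collapsed to the triple formulas; the residual
  error of that collapse is far below the oracle tolerances but is not
  zero.

## Reproducing the headline numbers

```{r validation}
res <- run_validation()
res$speed      # thermal wave speed, m/s
res$arrival    # detected arrival at x = 2 mm, s
```

```{r model}
m <- bioheat_model(bioheat_params())
summary(m)
```
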