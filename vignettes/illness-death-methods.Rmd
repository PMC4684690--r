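---
title: "Methods: prevalence, incidence and mortality in the illness-death model"
author: "illnessdeath package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prevalence, incidence and mortality in the illness-death model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

The package works with the irreversible three-state compartment model of
chronic-disease epidemiology: individuals are *Healthy*, *Diseased* or
*Dead*. The transitions are governed by three hazards — the incidence
$i(t,a)$, the mortality of the healthy $m_0(t,a)$ and the mortality of the
diseased $m_1(t,a,d)$ — on three time scales: calendar time $t$, age $a$
and disease duration $d$.

Three structural assumptions are made throughout:

1. the population is closed (no migration);
2. the disease is contracted after birth, so the prevalence at age 0 is 0;
3. the cohort densities are smooth enough for the balance equations to hold.

Writing $S(t,a)$ for the healthy and $C(t,a,d)$ for the duration-resolved
diseased density of a birth cohort, the balance equations

$$(\partial_t+\partial_a) S = -(m_0+i)S, \qquad
  (\partial_t+\partial_a+\partial_d) C = -m_1 C,$$

with $C(t,a,0) = i(t,a)\,S(t,a)$, have explicit exponential solutions along
the characteristic (cohort) lines $t-a=\mathrm{const}$. The age-specific
prevalence is $p = C^*/(S+C^*)$ with $C^*(t,a)=\int_0^a C(t,a,\delta)\,
d\delta$.

### The three computational routes

**Duration integral** (`prevalence_keiding()`). Substituting the explicit
solutions gives

$$p(t,a)=\frac{\int_0^a i(t-\delta,a-\delta)\,\mathcal M_{t,a}(a-\delta)\,
  e^{-M_1(t,a,\delta)}\,d\delta}
  {\mathcal M_{t,a}(a)+\int_0^a i(t-\delta,a-\delta)\,
  \mathcal M_{t,a}(a-\delta)\, e^{-M_1(t,a,\delta)}\,d\delta},$$

with $\mathcal M_{t,a}(y)=\exp(-\int_0^y m_0+i)$ evaluated along the
characteristic and $M_1(t,a,d) = \int_0^d
m_1(t-d+\tau,a-d+\tau,\tau)\,d\tau$ the cumulative mortality over a disease
spell. Because the expression is a ratio, the birth-cohort size cancels; the
implementation therefore fixes $S_0 \equiv 1$ and does not produce absolute
case counts. The same cancellation removes every survival factor accumulated
below the incidence minimum age, so hazards are never evaluated at ages
where the incidence model does not apply (for the dementia example, below
age 50).

**Prevalence PDE** (`solve_prevalence_pde()`). The prevalence solves

$$(\partial_t+\partial_a)\,p = (1-p)\bigl(i - p\,(m_1^*-m_0)\bigr),
  \qquad p(t,0)=0,$$

where $m_1^*(t,a)$ is the $C$-weighted mean of $m_1(t,a,\cdot)$ over the
durations present in the diseased pool (`m1_star()`), with $m_1^* = m_1$
exactly when $m_1$ does not depend on duration. Along a characteristic the
directional derivative becomes an ordinary derivative in age, and the
initial-value problem is integrated per cohort.

$m_1^*$ inside the PDE depends on the duration distribution of the
prevalent cases, which is itself part of the model solution. The package
breaks this circularity by computing $m_1^*$ from the closed-form duration
density (the same $C$ as in the integral route). The equivalence of the two
routes for duration-independent $m_1$ — an identity, not an approximation —
is asserted in the test suite to $10^{-6}$ absolute on the full benchmark
grid, and in practice holds to ~$10^{-11}$.

**General-mortality form** (`solve_prevalence_general()`). When only the
whole-population mortality $m = p\,m_1^* + (1-p)\,m_0$ and the relative
mortality $R=m_1^*/m_0$ are available (life tables plus a disease-specific
survey), the excess-mortality term can be rewritten through the population
attributable fraction $\mathrm{PAF} = p(R-1)/(p(R-1)+1)$:

$$(\partial_t+\partial_a)\,p = (1-p)\left(i - m\,
  \frac{p(R-1)}{p(R-1)+1}\right).$$

### The inverse problem

Solving the PDE for $i$ gives
$i = (\partial_t+\partial_a)p/(1-p) + p\,(m_1^*-m_0)$. With two
cross-sectional surveys at $t_0$ and $t_0+\Delta$, both the mid-survey
prevalence and its directional derivative are approximated along the cohort
direction:

$$p(\tilde t,a) \doteq \tfrac12\left[p(t_0+\Delta,a+\tfrac\Delta2)
  + p(t_0,a-\tfrac\Delta2)\right], \qquad
 (\partial_t+\partial_a)p \doteq \tfrac1\Delta\left[
  p(t_0+\Delta,a+\tfrac\Delta2) - p(t_0,a-\tfrac\Delta2)\right].$$

Both are exact for prevalence surfaces linear in $(t,a)$ — the two shifted
evaluation points lie on the same characteristic as $(\tilde t, a)$ — so
the estimator error is a pure linearization (curvature) error plus whatever
error the supplied mortalities carry.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `relative_tolerance` | `quadrature_settings()` | $10^{-8}$ | target relative accuracy of every quadrature |
| `absolute_tolerance` | `quadrature_settings()` | $10^{-12}$ | absolute floor for near-zero integrals |
| `max_refinements` | `quadrature_settings()` | 18 | interval halvings before a numerical-failure error |
| `step_size` | `characteristic_settings()` | 0.05 y | RK4 age step along a characteristic |
| `start_age` | `characteristic_settings()` | incidence min. age | where $p=0$ is imposed |
| `m1_star_grid_step` | `characteristic_settings()` | 0.5 y | spacing of the precomputed $m_1^*$ grid (duration-dependent case) |

The quadrature default is chosen so that the benchmark table is stable to
all 7 printed decimals under a 10-fold tightening (asserted in the tests).
The RK4 step of 0.05 years makes the $O(h^4)$ discretisation error
negligible against the quadrature tolerance; fourth-order convergence is
verified empirically by step-halving.

## Numerical choices

* **Quadrature.** Smooth integrands (cumulative hazards of log-linear
  rates) use Romberg extrapolation with the prescribed-accuracy stopping
  rule; the extrapolation depth is capped at 10 columns because deeper
  columns only amplify rounding error. Integrands assembled from cached
  spline interpolants are only piecewise-smooth in higher derivatives, so
  they use doubling composite Simpson instead, where Richardson
  extrapolation would stall.
* **Cumulative-hazard caching.** For each target $(t,a)$ all inner
  integrals run along one characteristic; the cumulative hazards are
  integrated once on a refined grid (doubling until two successive
  interpolants agree within a tenth of the tolerance) and interpolated by a
  monotone Hermite spline.
* **Discontinuities.** The incidence switches on at its minimum age, and
  piecewise-constant duration profiles jump at their breakpoints. All
  integrals are split there, and on every sub-interval but the last the
  upper endpoint is nudged inward by a relatively negligible $10^{-12}$ so
  that the right-continuous convention does not leak the post-jump value
  into the preceding segment.
* **Characteristic start.** Below the incidence minimum age the prevalence
  is identically 0, so integration always starts there; this keeps RK4
  stages away from the incidence discontinuity and makes the solution
  exactly independent of any earlier requested start age.
* **Degenerate $p \to 1$.** If the healthy survival underflows to 0 the
  prevalence would round to 1 and the inverse formula would divide by 0;
  the forward model raises a numerical-failure error (carrying the achieved
  estimate) rather than returning 1.
* **$m_1^*$ interpolation.** In the duration-dependent PDE route, $m_1^*$
  is precomputed on an age grid and spline-interpolated at the RK4 nodes;
  at grid nodes where the diseased pool is still empty the defining ratio
  is 0/0 (returned as 0 by convention), and the interpolant instead uses
  the newest-case limit $m_1(t,a,0)$ — the solution is unaffected because
  $p=0$ there, but the spline no longer overshoots at the onset boundary.
* **Determinism.** No Monte Carlo is used anywhere; repeated runs are
  bit-identical.

## The simulated study (what the generator emulates)

The packaged study conditions are those of the dementia-in-German-males
example that fully specifies the benchmark: healthy mortality
$m_0(t,a)=\exp(-9.0+0.085a-t\ln 1.01)$ with $t$ in years since 1960 (an
approximation to official male mortality, with a 1% secular annual
decline), time-constant incidence $i(a)=\exp(-12.8+0.11a)$ from age 50, and
relative mortality $R=2.63$, the published average over the first six years
after a dementia diagnosis. Two surveys are simulated at 2010 and 2015
($\Delta = 5$ years) on the age grid $60, 62.5, \ldots, 100$, and the
estimation is carried out at the 15 interior ages $62.5,\ldots,97.5$.

What the simulation does *not* emulate: sampling noise (surveys are finite
samples; here the generated prevalences are exact to quadrature accuracy),
migration, secular trends in incidence, diagnostic misclassification, and
reversible disease courses. Passing tests therefore demonstrate the
*method* error — linearization plus numerics — not robustness to survey
noise; confidence intervals and bootstrap error bounds are out of scope.

The duration-dependent variant (`run_duration_experiment()`) generates the
surveys under $m_1(t,a,d) = R(d)\,m_0(t,a)$ with a user-supplied
piecewise-constant profile $R(d)$, and estimates either with an assumed
constant (or age-stepped) relative mortality — quantifying the
misspecification bias — or with the exact $m_1^*$ of the generating model,
which isolates the pure linearization error. No specific published $R(d)$
profile ships with the package, because the year-by-year values underlying
the motivating study are not part of the model specification; users supply
their own.

## Design decisions

* Calendar years are converted to model time ($t=0$ at `time_origin`,
  default 1960 for the dementia rates) at the interfaces; all internal rate
  evaluation uses model time. Rates are extrapolated outside any fitted
  range (cohort integrals for old ages reach before the origin); no
  clamping is applied.
* Duration profiles are right-continuous at their breakpoints; the choice
  is a convention, made explicit in `eval_duration_profile()`.
* The estimator requires the shifted ages $a \pm \Delta/2$ to be survey
  grid points; monotone cubic interpolation is available behind an explicit
  `interpolate = TRUE` flag and is off by default, so no silent
  interpolation error enters the estimates.
* Negative incidence estimates are reported with a warning, never clamped:
  they are a diagnostic for inconsistent inputs (e.g. prevalence falling
  faster than excess mortality can explain).
* A survey lag is inferred from the two survey times; a non-positive lag is
  an error.

## Problem sizes used by the test-suite

The suite runs the full benchmark (2 surveys × 17 ages, then 15 estimation
ages) several times, the cross-route equivalence on the full 2 × 17 grid,
the duration-dependent experiments on a reduced 9-age grid (70–90 years),
and a 10-replicate random-parameter recovery study. These sizes keep a
complete run in the minutes range while exercising every code path; all
results quoted above are recomputed by the suite at run time.

## Known limitations

* The inverse estimator divides by $1-p$: as prevalence approaches 1
  (e.g. implausibly large incidence parameters), the linearization error is
  amplified without bound and recovery accuracy degrades sharply; with
  double-precision survey values the estimator fails outright when $p$
  rounds to 1. The ~2% recovery accuracy observed in the benchmark is a
  property of the benchmark's regime ($p \lesssim 0.25$), not a universal
  guarantee.
* The midpoint/central-difference approximations carry an error growing
  with the cohort-direction curvature of $p$ over the lag $\Delta$; at the
  benchmark's conditions it is about $10^{-3}$ absolute in prevalence at
  age 80.
* $m_1^*$ cannot be identified from two cross-sections alone; when the true
  diseased mortality is duration-dependent, the estimates inherit the bias
  of the assumed relative mortality (illustrated by the duration
  experiment's high-age underestimation).
* Absolute counts, migration, remission and sampling error are out of
  scope.
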