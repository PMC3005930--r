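---
title: "Gradient matching for gene-network ODE models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient matching for gene-network ODE models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdagrn)
```

## The estimation problem

A gene network of $N$ genes is modeled by the ODE
$\dot{\mathbf x} = \mathbf f(\mathbf x, \theta)$, where $x_g$ is gene $g$'s
expression level and $\theta$ collects kinetic and regulatory parameters.
The classical trajectory-based criterion
$E_{\mathrm{traj}}(\theta) = \sum_j \lVert \mathbf x(t_j) - \mathbf y(t_j)\rVert^2$
requires a numerical ODE solution per evaluation and is severely non-convex.

`fdagrn` implements the functional-data-analysis alternative. Each observed
series is interpolated by cubic splines, giving a differentiable smooth
$\hat{\mathbf y}(t)$, and parameters are chosen to reproduce the *estimated
derivatives*:
$$E_0(\theta) = \sum_i \int \bigl\lVert \tfrac{d\hat{\mathbf y}^i}{dt}(t)
  - \mathbf f(\hat{\mathbf y}^i(t), \theta)\bigr\rVert^2\, dt ,$$
where $i$ ranges over series and $t$ over each series' observed duration
(never beyond it — extrapolated spline derivatives are meaningless).
Evaluating $E_0$ needs only the dynamics function along the smooth, never an
integration; the package counts integrator invocations
(`ode_solve_count()`) so this property is testable rather than assumed.
Because each gene's parameters $\theta_g$ enter only its own component
$f_g$, $E_0$ splits into $N$ independent per-gene regressions — the
decomposition the enumeration module exploits.

## The gene model

Each modeled gene follows
$$\dot x_g = R_g\, \sigma\!\Bigl(\sum_{g'} T_{gg'}\, x_{g'} + h_g\Bigr) - \lambda_g x_g,$$
with maximum production rate $R_g$ (expression units per time), regulatory
weights $T_{gg'}$ (per expression unit; positive = activation, negative =
repression, structurally zero when $g'$ is not a candidate), dimensionless
bias $h_g$, and first-order decay $\lambda_g$ (per time). The sigmoid
$\sigma$ maps summed regulatory input to a production fraction in $(0,1)$.
Its exact form is a genuinely open choice in this model class; the package
defaults to the logistic $1/(1+e^{-u})$ (computed in an overflow-safe split
form) and offers the algebraic form
$\tfrac12\bigl(u/\sqrt{u^2+1}+1\bigr)$ common in gene-circuit studies.
Both are bounded, symmetric and strictly increasing; the choice is recorded
in every serialized model. Genes without regulatory inputs among the
measured genes (e.g. maternal gradients in the gap-gene setting) are not
modeled: their trajectories enter the right-hand side as exogenous inputs
taken from the data splines.

## Smoothing choices

Splines are *interpolating*, not penalized: the data regimes this method
targets are either heavily pre-averaged (gap-gene-style imaging data) or
noiseless-by-construction benchmarks, and the optional `presmooth()`
moving average covers mild noise. The end condition is not-a-knot — third
derivative continuous across the second and penultimate knots — which is
the standard default and, for exactly four points, reproduces the unique
interpolating cubic. A natural-spline variant is available
(`end_condition = "natural"`); on well-sampled series the difference is
confined to the end intervals. Neither base R nor the installed numerical
add-ons expose a not-a-knot interpolant with coefficient access, so the
tridiagonal construction is implemented in the package and verified in the
tests against an independent brute-force linear-system oracle. At least
four points per series are required; non-monotone time grids are rejected.

Derivatives come from differentiating the piecewise-polynomial
coefficients. The test suite checks interpolation at knots to $10^{-9}$,
third-derivative continuity at the not-a-knot knots, and convergence of
central differences to the analytic derivative.

## Numerical choices

* **Quadrature.** The error integral uses composite trapezoid quadrature on
  a uniform subgrid with 5 subdivisions per knot interval
  (`quadrature_points_per_interval`). Density-doubling changes $E_0$ by
  about $10^{-4}$ relative for generic parameters on the standard
  benchmark, comfortably within the convergence the fits need. Note the
  check is made with a smooth $O(1)$ residual; at the generating truth the
  residual is dominated by sub-grid spline wiggle and relative changes are
  uninformative.
* **Optimizer.** Per-gene minimization uses bounded L-BFGS-B with analytic
  gradients, from `n_starts` random starts drawn uniformly within the
  parameter box; the lowest-error start wins, ties resolved by the lowest
  start index. The default budget is 1000 starts; the tests use 25–50,
  which on the packaged benchmarks already reaches the same optima. Start
  draws are seeded per (target, regulator-set), so per-gene results are
  identical whether a gene is fit alone, inside `fit_network()`, or inside
  an enumeration, and are independent of target order.
* **Bounds presets.** `"drosophila"` (native 0–255 intensity scale):
  $T \in [-0.1, 0.1]$, $R \in [0, 25]$, $\lambda \in [0, 10]$, bias fixed
  at $-3.5$; `"irma_gnw"` (mRNA data rescaled so the maximum is 100 via
  `normalize_to_range()`): $T \in [-0.2, 0.2]$, $R \in [0, 25]$,
  $\lambda \in [0, 10]$, $h \in [-25, 25]$. The weight-zero threshold
  0.006 applies on the fitted scale and is deliberately strict:
  $|T| < 0.006$ is zero, $|T| = 0.006$ keeps its sign.
* **Integration** (simulation and trajectory-based error only): adaptive
  ode45 with absolute/relative tolerances $10^{-8}/10^{-6}$; a fixed-step
  classical RK4 is available and its 4th-order convergence is asserted in
  the tests against a hand-coded stepper.
* **L1 path.** $E_1 = E_0 + c \sum |T|$ penalizes regulatory weights only.
  The default grid is $c = 0, 0.1, \dots, 10$ (101 values); each $c$ is
  refit from the same seeded starts (warm-starting would only be a speed
  optimization and is not used, keeping per-$c$ results independent).
  There is no principled universal rule for choosing one $c$ from time-series
  data, so the path and the per-link maximal surviving $c$
  (`link_confidence`) are reported instead of a single model.
* **Sub-gradient at zero.** The L1 term uses `sign(T)` in the gradient
  (zero at $T = 0$); L-BFGS-B tolerates this, and exact zeros are not
  required because thresholding, not the penalty, makes the final call.

## Enumeration

With $K$ candidate regulators a gene admits $2^K$ regulator subsets;
`enumerate_gene()` fits them all (bitmask order, ties to the smaller mask)
and `best_per_size` reports the error-minimizing subset of each size,
annotated with the added regulator when the optimum of size $k$ extends the
optimum of size $k-1$ (non-nested optima are reported as the full subset).
The per-gene decomposition means a whole network costs
$\sum_g 2^{K_g}$ independent fits — `enumeration_plan()` exposes exactly
this combinatorial count. `best_k_architecture()` assembles the size-$k$
optima into a network and thresholds it, giving a regularization-by-degree
alternative to the L1 path; `lattice_table()` exports every subset with
ranks and an inverse-error score for lattice-style displays.

## Scoring signed networks

`compare_networks()` scores over all candidate (regulator, target) pairs,
excluding self-pairs when autoregulation is disallowed. CF is the fraction
of $-/0/+$ calls matching the gold standard; TP/TN/FP/FN are sign-blind
(TP = nonzero in both networks); PPV = TP/(TP+FP), sensitivity =
TP/(TP+FN); CSF is the fraction of TP pairs with matching sign. Fractions
with empty denominators are reported as `NA`, never 0, and serialize as
empty fields — silently coding "undefined" as 0 would deflate summaries.
Chance-level CF under uniform random signing is exactly 1/3 for any gold
standard, which the tests confirm by Monte Carlo.

## What the synthetic data emulate — and what they do not

The generator (`generate_benchmark()`) draws sparse or dense signed
topologies without autoregulation and parameters strictly inside the
`irma_gnw` bounds: weight magnitudes in $[0.05, 0.15]$ (above threshold,
inside the box), $R \in [8, 20]$, $\lambda \in [0.8, 2]$, $h \in [-3, -1]$.
The standard recovery benchmark uses 5 genes, 20 noiseless series of 16
points over 6 time units — the 0.4 sampling interval resolves the fastest
decay timescale ($1/\lambda \ge 0.5$), which is what makes spline
derivatives accurate enough for exact sign recovery. Two protocols are
implemented: independent random initial conditions, and perturb-then-relax
(transient 2.5× overexpression of a rotating gene from the steady state,
with only the relaxation half returned, so the data describe unperturbed
dynamics). Everything is keyed to a single seed and reproduces exactly.

The gap-gene- and IRMA-shaped fixtures reproduce the *dimensions,
conventions and gold topologies* of those reference data sets — 7 genes ×
8 times × 58 spatial series on a 0–255 scale with 4 modeled targets and
28 candidate pairs; 5 genes × 5 series on a 20-minute grid over 5 hours
with a 7-edge gold standard — but they are simulated stand-ins, not the
real measurements. Consequently the package's passing benchmarks
demonstrate correctness of the machinery and recoverability under
model-matched, noise-free conditions; they do not certify performance on
real data, where model mismatch (delays, protein/mRNA separation,
measurement noise, unobserved regulators) dominates. The spatial fixture
also treats the 58 positions as independent series — time is the only
spline axis, and no diffusion between positions is modeled.

## Known limitations

* Interpolating splines pass through noise; for noisy series use
  `presmooth()` or more series rather than expecting the fit to denoise.
* Multi-start local search carries no global-optimality guarantee; the
  tests assert it at least ties the generating truth and an 11-point
  parameter lattice on the packaged problems.
* The L1 sub-gradient treatment gives near-zero, not exactly zero, weights;
  conclusions about sparsity should go through the threshold or the
  enumeration, not through counting exact zeros.
* One sigmoid per network; per-gene sigmoid choices, delays, and
  knock-out/over-expression designs are out of scope.

## Problem sizes used in the checks

The packaged test and acceptance runs use the 5-gene recovery benchmark
(20 series, 50 starts per gene), a hand-built 3-gene ring for enumeration
and oracle-equivalence checks (8 series, up to 25 starts), an
11³-point lattice for the grid-search comparison, and 10,000 Monte-Carlo
draws for the chance baseline — sizes at which every documented property
is exercised in a few minutes on one CPU.
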