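---
title: "Local linear Poisson regression by locally kernel-weighted maximum likelihood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local linear Poisson regression by locally kernel-weighted maximum likelihood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locpoisreg)
```

## The model

`locpoisreg` estimates the conditional mean of a count response
$Y_i \sim \mathrm{Poisson}(\theta(x_i))$ with the canonical log link
$\theta(x) = \exp(m(x))$, where $m(\cdot)$ is an unknown smooth function of
$p$ numeric predictors. Instead of assuming $m$ is globally linear (the
ordinary Poisson GLM, kept in the package as the baseline `fit_global()`),
the estimator expands $m$ to first order around an evaluation point $x_0$,

$$m(x_i) \approx \beta_0(x_0) + \sum_{j=1}^p \beta_{1j}(x_0)\,(x_{ij} - x_{0j}),$$

and maximizes the kernel-weighted Poisson log-likelihood

$$\ell(\beta; x_0) = \sum_{i=1}^n w_i(x_0)\left[\,y_i \eta_i - e^{\eta_i}
  - \ln(y_i!)\,\right],\qquad
  w_i(x_0) = \prod_{j=1}^p K_{h_j}(x_{ij} - x_{0j}),$$

with $\eta_i$ the centered linear predictor. The intercept
$\beta_0(x_0)$ is the estimated log-mean *at* $x_0$ (the centered row at
$x_0$ is $(1, 0, \dots, 0)$), and the slopes are the local partial
derivatives of $m$. Fitting this at every observation point yields one
local model per observation (`fit_at_observations()`, assembled by
`llp_model()`), each with a validity window
$(x_{0j} - h_j,\, x_{0j} + h_j)$ per predictor inside which the Taylor
approximation is trusted.

Assumptions: counts are conditionally Poisson (equidispersed given $x$;
`dispersion_check()` reports the marginal variance-to-mean ratio, which can
greatly exceed 1 when the mean itself varies strongly across observations,
as in the shipped fixture), $m$ is smooth, and predictors are numeric.
Overdispersed families (quasi-Poisson, negative binomial) are out of scope.

The score, Hessian and Fisher information have the standard weighted-GLM
forms

$$g = X_c^\top W (y - e^\eta), \qquad
  H = -X_c^\top V X_c, \quad V = \mathrm{diag}(w_i e^{\eta_i}), \qquad
  I = -H,$$

with $X_c$ the centered design. Two parameterization choices deserve note,
both forced by identifiability:

* **Single intercept.** A formulation with one intercept per predictor is
  not identifiable — only the sum of the intercepts enters the linear
  predictor — so the parameter vector has length $p + 1$.
* **Kernel weights in the curvature.** The diagonal of $V$ carries
  $w_i e^{\eta_i}$, not $e^{\eta_i}$ alone; otherwise the Newton update
  would not solve the *weighted* score equations it is paired with.

## Fitting: Newton–Raphson with safeguards

`newton_raphson()` iterates $\beta \leftarrow \beta + I^{-1} g$ and stops
when $\lVert\Delta\beta\rVert_2 \le \varepsilon$ (default
$\varepsilon = 10^{-6}$, `max_iter = 100`; both are exposed in
`fit_options()` since no universal values exist). Numerical choices:

* **Initialization.** The classical start is OLS of the *raw counts* on the
  raw predictors, recentred to $x_0$ coordinates. On data with large counts
  this start puts the linear predictor at the count scale (hundreds), far
  above the log-scale optimum, where Newton needs one iteration per unit of
  excess log-mean or overflows outright. The fitter therefore evaluates
  both the OLS start and a log-mean fallback
  $(\ln(\max(\bar y_w, 1)), 0, \dots, 0)$, with $\bar y_w$ the
  weight-averaged response, and keeps whichever has the higher weighted
  log-likelihood. The OLS start also yields to the fallback when the raw
  design is rank deficient.
* **Safeguard.** Step-halving (up to 30 halvings) whenever a step would
  decrease the log-likelihood or overflow $e^\eta$; accepted steps never
  decrease the likelihood. `safeguard = FALSE` recovers the plain update.
* **Ridge.** `ridge * trace(I)/(p+1)` (default $10^{-10}$) is added to the
  diagonal of $I$ before the linear solve (never an explicit inverse), so
  nearly collinear centered designs — e.g. duplicated predictor values
  under a narrow kernel — remain solvable. A system that is singular even
  then raises a fit error naming $x_0$.
* **Degenerate neighbourhoods.** If all product-kernel weights vanish
  (compact kernel, isolated $x_0$) the design is rejected; additionally a
  fit is refused when $\sum_i w_i < 10^{-2}\, n \max_i w_i$, i.e. when one
  observation carries essentially all the local mass.
* `ln(y_i!)` is computed as `lgamma(y + 1)`, so counts in the hundreds do
  not overflow.

## Kernels and bandwidths

The kernel family is Gaussian by default — always-positive weights keep the
local likelihood well defined at every evaluation point — with Epanechnikov
($0.75(1-u^2)$ on $|u| \le 1$) as the compact-support alternative; this
follows common practice in the local-likelihood literature, which typically
leaves the kernel choice open. The scaled kernel uses the density
convention $K_h(t) = K(t/h)/h$. The $1/h$ factor cancels in the score
equations, so estimates are invariant to it; only reported weight and MLCV
magnitudes depend on the convention. Weights are deliberately *not*
renormalized: ratios are all that matter.

Bandwidths are in the units of their predictor. Small $h$ tracks local
fluctuations at the cost of variance; large $h$ recovers the global GLM
(the constant-weight limit, which the test suite checks at
$h = 10^3 \times$ the predictor range).

`select_bandwidth()` maximizes leave-one-out MLCV on a user-supplied grid,
in two modes: `joint` scans a list of complete bandwidth vectors
exhaustively; `per_predictor` (default) scans each coordinate's
one-dimensional grid while holding the other coordinates fixed (at their
grid midpoints before they are scanned, at their selected values after),
in a single pass — the presentation used in per-predictor bandwidth tables.
The leave-one-out value $\hat m_{-i}(x_i)$ is the centered intercept of
the local fit at $x_0 = x_i$ on the row-deleted data, implemented by
explicit row deletion. Failed leave-one-out fits are dropped from the sum
with a recorded count rather than aborting (compact kernels at small $h$
routinely isolate points); a grid point with more than 20% failures is
marked invalid (`NA`) and excluded from the argmax. Ties break to the
earliest grid point, making selection deterministic. Continuous
optimization of MLCV and plug-in bandwidth rules are non-goals; the grid
is the interface.

## Prediction

`predict()` offers two strategies. `refit` (default) fits a fresh local
model at each query point — statistically correct anywhere in the predictor
space. `nearest_fit` evaluates the stored local model whose centre is
closest in bandwidth-scaled Euclidean distance (ties to the lowest index),
mirroring workflows where one model per district is published and queried.
Evaluating a stored fit outside its validity window warns rather than
errors: extrapolating a published local model slightly beyond its window is
an accepted, if approximate, use and should not crash a batch. Rounding to
whole cases is opt-in (`round_mode = "nearest"`); the model's natural
output is a positive real mean.

## The synthetic-data generator

The method's motivating data — district-level stunting counts with two
coverage percentages — is confidential, so `simulate_counts()` provides
the statistical structure the estimator assumes, and
`stunting_fixture()` ships one fixed 39-row realization
(`inst/extdata/stunting_synthetic.csv`, fully synthetic, regenerable from
scenario seed 49) that emulates the published descriptive statistics:
counts with mean near 110, standard deviation near 197 and a long upper
tail, and right-skewed percentage predictors with means near 4.06 and 7.28
on ranges 0–21.43 and 0.75–30.01. The `stunting_like` scenario draws
predictors from scaled Beta laws matched to those means and adds a
log-normal heterogeneity term (sd 1.15) to the log-mean: a deterministic
function of two bounded predictors cannot produce both a mean of ~110 and
a maximum of ~836, whereas unobserved district-level heterogeneity —
standard in small-area epidemiology — does, while each count remains
conditionally Poisson.

Other scenarios have exact, noise-free truths used in recovery tests:
`log_linear` (default coefficients $(1, 0.5, -0.3)$ on uniform $[0,2]$
predictors), `quadratic`, and `sinusoidal`
($m = 2 + \sin(2\pi x)$ on $[0,3]$ by default), the canonical
strongly-non-log-linear surface on which local fitting beats the global
GLM. A mean cap (default $10^4$) rejects scenarios that would overflow.
What the generator does *not* emulate: spatial correlation between
districts, measurement error in the percentages, and real-data artefacts
such as heaping — so passing tests demonstrate correctness of the
estimator under its own assumptions, not performance on real survey data.

## What the tests establish, and at what scale

The suite verifies: kernel identities and product-weight oracles; analytic
score/Hessian against central finite differences (50 random instances,
$n \le 20$, $p \le 3$); exact agreement of the unit-weight Newton fitter
with an independent IRLS GLM implementation (100 instances at $n = 100$,
$p = 2$, max-abs difference $\le 10^{-8}$); the constant-weight limit on
the 39-row fixture; MLCV against an independently coded leave-one-out loop
(explicit deletion, prior-weight IRLS, explicit log-density summation;
$n = 30$, $3\times3$ grid, agreement $\le 10^{-9}$); slope recovery at the
predictor-space centroid on log-linear simulations ($n = 2000$, 50
replicates, absolute bias $\le 0.02$) with 3-standard-error coverage of
the global fit in $\ge 95\%$ of replicates; and the localization benefit
(MLCV at $h = 0.2$ versus $h = 10^3$ on a sinusoidal truth, $n = 60$).
These sizes were chosen as the smallest at which each property is sharply
distinguishable from noise under fixed seeds.

## Limitations

* One local model per evaluation point: $n$ Newton solves per full fit and
  $O(n^2)$ solves per MLCV evaluation; grids should stay modest for
  $n$ in the thousands.
* No interval estimation: Fisher information is computed and stored, but
  Wald/likelihood inference on local coefficients is not provided.
* The MLCV scale depends on the kernel convention and on dropped failure
  terms; MLCV values are comparable across bandwidths on the same data,
  not across datasets.
* Boundary bias is mitigated (local linear, not local constant) but not
  eliminated; windows near the predictor-range boundary lean on one-sided
  data.
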