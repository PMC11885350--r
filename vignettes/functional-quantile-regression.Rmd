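---
title: "Quantile regression for longitudinal functional data: models and methods"
author: "funqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile regression for longitudinal functional data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funqr)
```

## The model

`funqr` estimates conditional quantiles of a scalar response observed
repeatedly for each of `N` subjects, where each observation carries a
functional covariate — a curve over a bounded continuum, in the motivating
setting a daily profile sampled on a dense within-day grid. Writing
`Y_ij` for observation `j` of subject `i`, taken at longitudinal time
`t_ij` with covariate curve `X_ij(s)`, the tau-quantile of `Y_ij` given
the covariate and the subject is modelled as

    Q_tau(Y_ij | X_ij, u_i)(t_ij) =
        alpha(t_ij) + INT beta(s, t_ij) X_ij(s) ds + u_i

with a smooth intercept `alpha(t)` over longitudinal time, a bivariate
coefficient surface `beta(s, t)` that lets the shape of the covariate
effect evolve over longitudinal time, and subject-specific levels `u_i`
with population mean zero. All of `alpha`, `beta` and `u` are specific to
the quantile level `tau`; the package fits one level at a time and makes
no attempt to prevent crossing of curves fitted at different levels (a
known property of separately fitted quantiles — check fitted levels
against each other before interpreting them jointly).

Identifiability caveats worth keeping in mind:

* `alpha` is identifiable because `u` is constrained to mean zero (the
  package enforces this exactly through an orthonormal contrast
  reparameterization);
* `beta(., t)` is identifiable only up to components orthogonal to the
  span of the observed covariate curves. Pointwise interpretation of the
  fitted surface should be cautious; integrated contrasts (see *Targets*)
  are the well-identified quantities.

## Basis representations and penalties

`alpha(t)` is represented in `L` cubic B-splines on equally spaced knots
over the observed time range (default `L = 10`). `beta(s, t)` is a
tensor-product smooth: `D` cyclic cubic B-splines in the within-day
direction `s` (default `D = 10`; cyclic so that the surface and its first
two derivatives agree at the two ends of the day) times the same
longitudinal basis as `alpha`. The functional covariate enters through
quadrature scores `xi_d = INT phi_d(s) X(s) ds`, computed with
trapezoidal weights on the observed grid (circular trapezoid — uniform
weights on an equally spaced grid — for the cyclic direction). A
left-endpoint rule is available (`rule = "left"` in
`functional_scores()`); on the dense grids targeted here the choice is
immaterial, and the trapezoid is second-order accurate.

Roughness is penalized by second-order difference penalties on the basis
coefficients (circular differences for the cyclic basis), one penalty per
direction of the tensor smooth so that smoothness in `s` and in `t` are
controlled separately, plus a ridge penalty `(lambda_u / 2) sum u_i^2` on
the subject levels. Model variants with `beta(s, t) = beta(s)`,
`beta(s, t) = beta(t) / |S|`-type integral effects, and a single scalar
coefficient on `INT X ds` are available for model comparison
(`compare_variants()`), reported with an extended log-F AIC and an
effective-degrees-of-freedom partition (smooth terms vs subject levels),
the latter computed as the trace of the influence matrix at the converged
working weights.

One numerical subtlety: the constant-in-`s` direction of the `beta` block
is annihilated by the difference penalties and is close to a data null
direction whenever `INT X ds` varies little across observations (typical
for daily profiles with a stable mean level). The fitter therefore adds a
fixed, tiny ridge (`1e-7` of the block's mean column energy) on the
covariate block, which resolves this near-flat ridge towards `alpha`
without materially biasing identified directions.

## The smoothed check loss

Estimation minimizes a penalized smooth approximation of the check
(pinball) loss: the extended log-F loss

    rho_lam(v) = (tau - 1) v + lam * log(1 + exp(v / lam)),

which is convex, twice differentiable, bounded between the check loss and
the check loss plus `lam * log 2`, and converges uniformly to the check
loss as `lam -> 0`. Smoothness makes damped-Newton optimization possible.
The default smoothness is `lam = 0.5 * sigma_r * M^(-1/3)` with `sigma_r`
a robust (MAD) residual scale from a penalized least-squares pilot fit
and `M` the number of observations — a standard bandwidth-order rule; it
can be overridden through `fq_config(elf_lam = )`. The pilot fit also
supplies the Newton warm start and the scale used in the extended log-F
log-likelihood behind the AIC.

The optimizer is a damped Newton iteration with Armijo line search,
Jacobi-scaled Cholesky solves (smoothing parameters can sit many orders
of magnitude above the data curvature), a trust-region cap on the step
length (far from the optimum with a very small `lam`, all logistic
weights can underflow and the Hessian degenerates), and a BFGS fallback.
Convergence is declared on a small gradient max-norm or a small Newton
decrement; because the logistic weights saturate in floating point for
`|v| > ~37 lam`, the iteration can land on a point where no descent
direction exists numerically although the gradient norm is not tiny —
that state is detected (no descent along the negative gradient at any
scale) and classified as converged, since the objective is convex.

## Smoothing-parameter selection

Smoothness penalties are chosen by subject-grouped 5-fold
cross-validation minimizing out-of-fold pinball loss, with held-out
subjects predicted at `u = 0` (the typical-subject quantile — the
quantity the model is for). `lambda_u` is chosen by *within-subject*
cross-validation: each subject's rows are spread over folds round-robin
and held-out rows are predicted including the subject's estimated
intercept. This split matters: a new-subject prediction at `u = 0` is
almost uninformative about how much the intercepts should be shrunk,
whereas within-subject prediction is directly sensitive to it. Fold
assignment is deterministic given the configuration seed. The search is
coordinate descent (two sweeps) over a log-spaced grid per parameter,
centered where the penalty and data terms balance.

Two picking rules are offered (`rule` in `select_smoothing()`), as in
standard cross-validated regularization practice. The default `"min"`
takes the CV minimum: pinball loss responds only second-order to
smoothing bias, so CV curves are flat near the optimum and any rule that
systematically prefers heavier smoothing converts that flatness into
first-order bias of the fitted curves — which matters because the
bootstrap machinery below cannot see smoothing bias (the bootstrap truth
is the already-smooth fitted curve). The `"1se"` rule (smoothest fit
within one fold-paired standard error of the minimum) is the conservative
choice for screening: under pure noise it reliably pushes the smooth
terms to the penalty null space. `lambda_u` always uses the one-SE rule:
it is a variance component, and full shrinkage in the absence of evidence
of subject-level variance is the analogue of a REML estimate sitting on
the boundary.

## Pre-smoothing noisy covariates

Raw covariate observations `W_ij(s_h) = X_ij(s_h) + noise` are smoothed
by functional principal component analysis before fitting
(`fit_fpca()`, `fpca_reconstruct()`): estimate the mean (raw
cross-sectional means by default — at the dense designs targeted the raw
mean is already stable, and not smoothing it keeps the projection exact
on noise-free input), smooth the sample covariance with a bivariate
tensor-product spline fitted to its off-diagonal entries (the diagonal
carries the measurement-error nugget), estimate the nugget as the average
gap between raw and smoothed diagonals, eigendecompose under the
quadrature inner product, and keep the smallest rank whose cumulative
eigenvalue fraction reaches the requested proportion of variance
explained (default `pve = 0.9999`, which retains essentially all visible
curve features while removing high-frequency noise). When the estimated
nugget is numerically negligible relative to the covariance trace the raw
covariance is eigendecomposed directly: smoothing exists to separate
noise from signal, and with no detectable nugget it would only add spline
approximation error. Scores are weighted least-squares projections
(curves here are dense and complete), and all observations are treated as
independent curves even when several come from the same subject — a
deliberate simplification; multilevel FPCA is out of scope.

## Targets and inference

Two functionals of the fit are supported:

* the **typical-subject quantile curve**
  `Q(t) = alpha(t) + INT beta(s, t) X(s) ds` at a reference curve `X`
  (`predict_quantile()`), and
* the **quantile difference**
  `D(t) = INT beta(s, t) (X_A(s) - X_B(s)) ds` between two reference
  curves for a fixed subject (`quantile_difference()`), in which `alpha`
  and the subject level cancel exactly.

Reference curves are often pointwise empirical quantiles of the observed
covariate sample (`pointwise_quantile_curves()`), e.g. a "cool day"
(pointwise 20%) versus a "warm day" (pointwise 80%) temperature profile.
Model-based standard errors use the delta method on the inverse penalized
Hessian; for the difference target only the `beta` block contributes, by
construction. Model-based intervals inherit the usual optimism of
penalized fits, which motivates the resampling machinery:

* `block_bootstrap()` resamples complete subjects with replacement,
  refits, and reports the per-time-point standard deviation of the target
  over replicates. Each selected subject's rows are carried verbatim, so
  within-subject dependence is preserved. Smoothing is held at the
  baseline values by default (`fix_smoothing = FALSE` re-selects per
  replicate at considerable cost).
* `wild_bootstrap()` estimates the refitting *bias*: responses are
  regenerated under a distribution whose true target equals the baseline
  estimate — fitted smooth part, plus subject levels resampled from the
  centered estimated intercepts, plus regenerated residual terms whose
  conditional tau-quantile is zero — with covariates held exactly fixed,
  and the mean deviation of the refitted target from the baseline
  estimate is the bias estimate.

The final interval is `estimate - bias ± z_(1-alpha/2) * sd_block`
(`confidence_interval()`, default 95%); `run_inference_pipeline()` chains
FPCA, fitting, both resampling schemes and the interval, with every
random draw governed by one seed. The default number of replicates is
`B = 100` per scheme.

Two design choices in the bias scheme deserve explanation, because the
package's own experiments drove them:

1. **Error regeneration.** The classical wild form multiplies each
   absolute residual by a two-point weight in
   `{2(1 - tau), -2 tau}` with `P(negative) = tau`; this guarantees the
   quantile-zero property but replaces the error distribution by two
   atoms. The refitting bias of a penalized quantile estimator, however,
   depends on the *shape* of the error distribution near its
   tau-quantile — both its attenuation component (subject-level mixing
   pulls the typical-subject curve towards the marginal quantile when
   intercepts are shrunk) and its small-sample component (per-subject
   quantile estimation from few repeated measures). In simulation the
   two-atom world reproduced neither and could even mis-sign the total.
   The default (`errors = "resample"`) therefore draws regenerated errors
   with replacement from the fitted residuals centered at their empirical
   tau-quantile, which preserves the shape while satisfying the same
   defining property exactly; it assumes the error distribution is
   exchangeable across observations. For covariate-dependent error scale,
   `errors = "wild"` restores the classical weights.
2. **Reflation of the intercepts.** Penalized estimates of `u` are
   shrunk; under the usual shrinkage analogy their mean square is about
   `(EDF_u / N)` times the subject-level variance. Resampling them raw
   would build a bootstrap world with too little subject heterogeneity
   and hence too little penalization bias, so the centered intercepts are
   rescaled by `sqrt(N / EDF_u)` before resampling, in the spirit of
   variance-reflated residual bootstraps for multilevel models.

Non-converged replicates are dropped with a warning when below 10% of
`B`; beyond that the run errors rather than report a silently biased
summary.

## The synthetic-data generator

`sim_truth()` / `simulate_dataset()` generate longitudinal functional
data with a fully known quantile structure; they are the basis of the
test suite and of the reproduction script. Defaults emulate the
*structure* of a lactation feed-intake study: around 225 subjects
(configurable), 7–21 consecutive daily observations each, covariate
curves on a 24-hour grid sampled every five minutes (`H = 288`) built
from a cyclic mean plus Fourier-type principal components (eigenvalues
4, 1, 0.25 in covariate units squared; measurement noise sd 0.25), a
subject level sd of 0.5 in response units, an intercept curve that rises
steeply over the first days before flattening, and a negative covariate
effect that strengthens over the observation period. Error families:
centered normal, t(3), and a centered, standardized chi-square(3) — the
skewed family included because low-quantile bias phenomena arise under
asymmetry. Longitudinal times are integer days; responses are built with
a fine-grid (10x) quadrature of the coefficient surface, and
`true_quantile()` returns the exact conditional quantile for any curve,
time, level and subject, which is the oracle behind all recovery tests.

What the generator does *not* emulate: the spectral content of real
barn-temperature curves, within-subject correlation of covariate curves
over days, missing days, or covariate-dependent error scale. Passing
tests therefore demonstrate correctness of the machinery under the stated
structure, not robustness to those features.

Problem sizes in the tests and the reproduction script are deliberate
desk-scale choices: reduced grids (`H` 48–96), `N` 25–100 and modest
basis dimensions exercise every code path at sub-minute fit times while
the Monte-Carlo components (bias reduction, bootstrap calibration,
coverage) use 30–100 outer replicates — enough to separate signal from
Monte-Carlo noise for the properties asserted, as the recorded z-values
in the test scenarios attest.

## Known limitations

* One quantile level per fit; no non-crossing constraints.
* The exchangeable-error assumption of the default bias scheme (see
  above).
* Model-based standard errors understate sampling variability in the
  presence of penalized intercepts; the block bootstrap is the supported
  route to honest standard errors.
* FPCA ignores within-subject dependence between curves.
* Smoothing bias is invisible to both resampling schemes (the bootstrap
  truth is the fitted, already-smooth curve); the default `"min"` CV rule
  keeps it small but cannot remove it.
* A single functional covariate and a single grouping level.
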