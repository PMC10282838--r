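---
title: "Boosted location-scale beta regression for PANSS factor totals"
author: "panssboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted location-scale beta regression for PANSS factor totals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panssboost)
```

## The outcome model

A PANSS factor with $n$ items has totals $y \in \{n, \dots, 7n\}$. We map
them to the half-open unit interval by

$$y_{\mathrm{rescaled}} = \frac{y - n + 1}{7n - n + 1},$$

so the minimum total lands at $1/(6n+1) > 0$ and the maximum at exactly 1.
Totals at the maximum are representable but excluded from likelihood
fitting, which needs the open interval; in the clinical setting that
motivated the package the maximum was not observed, and the synthetic
generator's defaults make it vanishingly rare. Rows that do reach it are
reported by `fit_factor_model()` as an input error rather than silently
dropped.

The rescaled outcome is modelled as beta-distributed with mean
$\mu \in (0,1)$ and scale $\sigma \in (0,1)$,

$$\mathrm{E}(X) = \mu, \qquad \mathrm{Var}(X) = \mu(1-\mu)\sigma^2,$$

which forces the shape parameters $\alpha = \mu s$, $\beta = (1-\mu)s$
with concentration $s = (1-\sigma^2)/\sigma^2$. Both parameters are
logit-linked to additive predictors $\eta_\mu$ and $\eta_\sigma$. Treating
a discrete proportion this way assumes the integer total approximates a
latent continuous severity — the justification for reporting summed
totals in the first place.

## Base learners and the fairness constraint

Binary covariates enter as 0/1 dummies, numeric covariates are
mean-centered with the *training* constants (held-out rows are centered
with the constants stored at fit time). Each of the 17 candidates gets a
penalized linear base learner, and each of the 8 numerics additionally a
P-spline learner for non-linear effects — 25 learners shared by the two
additive predictors.

Every learner is calibrated to **one effective degree of freedom**
(trace of its smoother matrix), so no learner is preferred merely for
flexibility:

* Linear learners are single-column, intercept-free least-squares fits —
  a rank-one projection with trace exactly 1 and no penalty. The global
  intercept lives in the model offset; including one per learner would
  force df = 2 and ridge shrinkage on the slope.
* P-splines use cubic B-splines over 21 equal segments spanning the
  observed range (20 interior knots) with a second-order difference
  penalty, reparameterized spectrally so the penalized directions carry
  an identity penalty and the penalty null space (constant and linear
  trends) is dropped — constants belong to the offset and linear trends
  to the linear learner. Without that decomposition a second-order
  penalty can never reach df = 1 (its null space alone contributes 2).
  The ridge constant solving $\mathrm{tr}(S_\lambda) = 1$ is found by
  bisection on $\log\lambda$ with automatic bracket expansion and
  tolerance $10^{-8}$; a dense grid search reproduces it to $10^{-4}$
  relative in the tests.

Two consequences are worth knowing. First, the reparameterized spline
basis is orthogonal to linear trends in *coefficient* space, not function
space, so a heavily penalized P-spline can still absorb a modest share
(about 15% of the energy on our cohorts) of a purely linear signal; the
linear learner fits such a signal exactly and therefore always wins
selection for it, which is the property that matters for the boosting
path. Second, covariates that are constant within a cross-validation fold
yield inert, never-selected learners instead of an error.

Knot count, penalty order, and the df definition ($\mathrm{tr}(S)$ rather
than $\mathrm{tr}(2S - S^\top S)$) are this package's documented choices:
standard P-spline practice, selected once and not revisited.

New data beyond the training knot range are evaluated by linear extension
of the boundary basis value and derivative, preventing cubic
extrapolation artifacts in partial-dependence grids.

## The non-cyclic boosting algorithm

Offsets come from a method-of-moments intercept model:
$\eta_\mu^{(0)} = \mathrm{logit}(\bar y)$ and
$\eta_\sigma^{(0)} = \mathrm{logit}\,\hat\sigma$ with
$\hat\sigma^2 = s^2 / (\bar y(1-\bar y))$ clipped to
$[10^{-6}, 1-10^{-6}]$. Offsets are never refit.

Each iteration:

1. compute the analytic gradients of the log-likelihood with respect to
   $\eta_\mu$ and $\eta_\sigma$ (parameters clipped to
   $[10^{-10}, 1-10^{-10}]$ as a numerical guard);
2. fit all 25 learners to each gradient vector by penalized least
   squares; the within-parameter winner is the best *fit* (smallest
   squared error), ties to the earlier learner;
3. form both damped candidates $\eta_p + \nu \cdot \mathrm{fit}$ with
   $\nu = 0.1$ and update only the parameter whose candidate attains the
   lower empirical risk (sum of negative log-likelihoods); risk ties
   (below $10^{-12}$) go to $\mu$.

The two-stage rule — least-squares fit within a parameter, realized risk
across parameters — is deliberate. A pure minimum-risk search over all 50
candidates almost always agrees (the first-order risk reduction of a
least-squares fit is monotone in its fitted energy) but can genuinely
differ at isolated iterations; the test suite pins the implemented rule
against an independently coded brute-force oracle of the same definition.

Empirical risk is the *sum* (not mean) of negative log-likelihoods, fixed
so logged risk values are reproducible. The risk sequence is
non-increasing, never-selected covariates have exactly zero accumulated
coefficients, and with a single linear learner per parameter the
algorithm at $m_{stop} = 1000$ reproduces the maximum-likelihood fit of
the model it optimizes (slopes free, intercepts at the stated offsets) to
machine precision. Its slopes also match a free 4-parameter ML fit within
0.02; the offsets themselves differ from free ML intercepts by an
$O_p(n^{-1/2})$ estimator difference (roughly 0.005–0.07 at $n = 500$)
that is a property of moment initialization, not of the boosting path.

One structural effect of intercept-free learners: when the scale
predictor needs a roughly constant correction (e.g. early in fitting,
while the location is still under-fit and the apparent variance is
inflated), that correction can only be expressed through covariates, and
uncentered binary dummies partially absorb it. Scale-parameter selections
of binary covariates early in the path should be read with that in mind.

## Tuning, validation, calibration

`select_mstop()` tracks the held-out mean negative log-likelihood along
the boosting path in k-fold cross-validation (default grid: every integer
up to the cap; the full-scale analysis caps at 1000) and returns the
grid value minimizing the fold average, ties to the smallest. Folds are
drawn uniformly without stratification; inner draws are re-randomized
per outer fold from the master seed.

`nested_cv()` repeats outer k-fold assessment around that inner tuning.
Optimism is reported as mean(train − test) for pseudo R² and
mean(test − train) for RMSE, so both are positive when apparent
performance flatters. Pseudo R² is the squared Pearson correlation of
$\mathrm{logit}(y_{\mathrm{rescaled}})$ with $\hat\eta_\mu$ — the same
scale the RMSE is computed on; whether the original analyses used the
logit or the proportion scale is not documented, and the logit scale was
chosen here for consistency between the two metrics.

Predictions are discretized back onto attainable totals with bin edges
midway between consecutive rescaled values and outer edges at exactly 0
and 1, so the masses telescope to 1 within $10^{-12}$. Because the
maximum total sits exactly at 1 under the half-open rescaling, the lowest
bin has width $1.5/(6n+1)$ and the highest $0.5/(6n+1)$: at $\mu = 0.5$
the pmf is exactly symmetric at all interior totals but not at the two
extremes. This is intrinsic to the stated rescaling, not a bin-placement
artifact; a uniform predictive density makes it visible as masses
$1.5/(6n+1)$ and $0.5/(6n+1)$ at the extremes.

Calibration uses the non-randomized PIT for discrete outcomes: an
observation with discretized CDF values $F_{lo} = P(Y \le y-1)$,
$F_{hi} = P(Y \le y)$ spreads unit mass uniformly over
$[F_{lo}, F_{hi}]$ (deterministic, hence exactly reproducible, unlike the
randomized PIT). Uniform histograms indicate calibration; depleted top
bins indicate over-forecasting. The chi-square uniformity check plugs the
fractional bin masses into the usual statistic with bins − 1 degrees of
freedom.

`loess_smooth()` wraps tricube-weighted local quadratic regression
(exact direct surface) on a 100-point grid for the qualitative
observed-vs-predicted displays.

## Interpretation

Variable selection frequency is the share of refitted models (across the
outer loop) in which any learner of a variable updated a given additive
predictor at least once. Partial dependence follows Friedman: the
variable is set to each grid value in every training row and predictions
are averaged over the empirical covariate distribution (not a model-based
one — the averaging set is this package's choice). Numeric grids span the
1st–99th training percentiles in 50 points to avoid extrapolation
artifacts; binary grids are $\{0, 1\}$. A second family of curves
averages the discretized score pmf instead, giving the marginal effect on
the probability of each attainable total; masses sum to 1 at every grid
value.

## The synthetic cohort generator

`generate_cohort()` stands in for the access-restricted clinical data.
Its defaults emulate the published admission profile of 320 admissions
for treatment-resistant psychosis:

* binary marginals — male 59.4%, schizoaffective 30.9%, prior clozapine
  trial 58.1%, clozapine 20.3%, antipsychotic polypharmacy 51.9%,
  antidepressant 21.9%, mood stabilizer 37.5%, benzodiazepine 31.9%,
  anticholinergic 20.6%;
* year of admission and age as normal fits to the printed median/IQR
  (2001.6 [1998.1, 2005.3]; 36.5 [27.0, 44.0], truncated at 18), PDD:DDD
  as a log-normal fit to 1.81 [1.09, 2.75] — two-parameter families
  because only those two summaries are printed;
* admission factor totals by discretizing factor-specific beta
  distributions matched to the printed medians and quartiles (e.g.
  positive 16 [13, 19], negative 19 [16, 22.25]), coupled by a Gaussian
  copula with a 0.4 correlation between the negative and disorganized
  factors (the two that predict each other most strongly); other pairs
  independent, since true covariate correlations are unknown;
* discharge totals from a configurable true model on the encoded
  covariates. The default truth gives each factor a single dominant
  effect of its own admission score — about 0.65 logits per
  admission-score standard deviation — an intercept placing the median
  discharge total at the published post-treatment level (12, 16, 9, 9, 6),
  and a constant scale $\sigma = 0.3$. The continuous draw is mapped to
  an integer by the same nearest-rescaled-value rule (`unrescale()`) the
  analysis side uses, keeping generation and discretization consistent.

These defaults define the regime the study describes — past scores
dominate future scores — and are not adjusted per experiment. What the
generator does **not** emulate: within-admission trajectories, diagnosis-
or treatment-specific response subgroups, covariate–covariate structure
beyond the single copula entry, item-level rating behaviour, or outcome
missingness patterns. Passing tests on this cohort therefore demonstrates
that the pipeline recovers a known truth of the assumed form at the study
size, not that the clinical findings replicate.

## Numerical and design notes

* Degenerate inputs: constant outcomes clip $\hat\sigma$ with a warning;
  constant covariates yield inert learners; non-finite candidate risks
  abort with iteration diagnostics; failed nested-CV fits are recorded,
  excluded from denominators, and counted in the result.
* The log-likelihood is strictly concave in $\eta_\mu$ on a wide
  neighbourhood of its maximizer, which is what stabilizes the damped
  updates; it flattens far out in the tails, so global concavity is not
  claimed (and is false).
* `unrescale()` breaks exact midpoint ties toward the smaller total;
  boosting ties go to $\mu$, then the earlier learner — all tie-breaks
  are deterministic, and identical master seeds give byte-identical
  result bundles (manifests deliberately carry no timestamps).
* Problem sizes in the shipped checks: nested CV at 5 repeats × 5 folds
  with 5-fold inner tuning and a path cap of 250 iterations on the
  320-row default cohort; calibration at 2000 observations; the
  acceptance run uses 2 × 5-fold outer loops per factor. These are the
  package's scaled study conditions for routine verification; the
  full-scale settings (100 × 10-fold outer, 10-fold inner, cap 1000)
  remain the defaults of `nested_cv()` and `run_full_analysis()`.

## Known limitations

* No zero/one-inflation: totals at the factor maximum cannot enter the
  likelihood; settings where the ceiling is common need an inflated
  variant.
* No interaction, spatial, or random-effect base learners; no stability
  selection; no confidence intervals for cross-validated estimates (the
  methodological question is open).
* Pseudo R² compares location predictors only; scale-model quality is
  assessed solely through calibration.
* Moment offsets are slightly inefficient relative to ML intercepts;
  with strong signals the initial scale offset absorbs signal variance
  and early scale-parameter selections partly compensate for it.
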