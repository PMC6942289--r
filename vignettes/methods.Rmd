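---
title: "Statistical methods behind ionrbe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind ionrbe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionrbe)
```

`ionrbe` analyses fractionated ion-beam toxicity experiments with a
binary late endpoint observed within a fixed follow-up horizon.  This
vignette explains the statistical model behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
cohort generator does and does not emulate.

## Endpoint and data model

The unit of observation is one animal: a total dose `D` (Gy, summed
over all fractions), an event indicator (1 if the endpoint — late
paresis grade II — occurred), the day of onset or of last observation,
and an exclusion flag for losses unrelated to the radiation response
(intercurrent deaths, second tumours).  Animals are grouped by the
exact printed dose level; no tolerance binning is applied, because
dose levels are design constants, not measurements.  Dose-0 control
groups are allowed and enter the fit like any other group.  Excluded
animals are dropped from the raw group size `n_raw` but kept in the
data model for audit, and they re-enter the actuarial stage as
censored observations — their incomplete follow-up is precisely the
information the correction accounts for.

## Actuarial response rates and effective sample sizes

A naive responder fraction `r/n` underestimates the complication
probability when animals leave observation before the horizon.  The
package therefore estimates the actuarial probability
`p_act = 1 − S(horizon)`, with `S` the Kaplan–Meier survivor function
of the event process: responders are events at their onset day;
animals dying or withdrawn without the endpoint are censored at their
last observation day.  This censoring convention is the standard
actuarial treatment for toxicity endpoints; it assumes censoring is
non-informative for the radiation response.

The variance attached to `p_act` is Greenwood's variance of
`S(horizon)` (an alternative binomial variance `p(1−p)/n` can be
selected through the `estimator` argument; the two coincide without
censoring).  The pair `(p_act, var_act)` is then converted into
*effective counts* that a binomial observation would have needed to
carry the same information:

```
n_eff = p_act (1 − p_act) / var_act,   r_eff = n_eff · p_act.
```

Two guard rules apply.  First, `n_eff` is capped at `n_raw`: censoring
can only lose information, and rounding noise in the variance must not
manufacture animals.  Second, degenerate groups (`p_act` of 0 or 1, or
zero variance) fall back to the raw counts, since the product-limit
estimator then carries no extra information.  With complete follow-up
the correction is exactly the identity, which the test suite verifies
end-to-end.  Variances are additionally floored at 0.25 (the maximum
binomial variance), which only matters for pathological single-animal
groups.

## Maximum-likelihood dose-response curves

Each experiment (one beam position and fraction number) is fitted with
a two-parameter sigmoid `p(D) = F(b0 + b1 D)`.  The default link is
logistic; probit is available, and near the 50% level — the only
region used downstream — the two are practically indistinguishable.
The binomial log-likelihood is evaluated with the real-valued
effective counts as weights; this is the natural continuous extension
of the binomial likelihood and the reason the fitter does not simply
call `glm` (which expects integer counts).  An independent `glm` fit
on integer-count data is used as a cross-check in the tests.

`TD50 = −b0/b1` for both links.  Its standard error comes from the
delta method using the full `(b0, b1)` covariance (inverse observed
information), and its 90% confidence limits from Fieller's theorem
applied to the ratio `−b0/b1` with the within-fit covariance — the
parameter correlation is therefore propagated, not ignored.  The
z-quantile (1.645 at 90%) is used rather than a t-quantile: after the
actuarial correction the effective sample size is real-valued and a
degrees-of-freedom basis for t would be arbitrary.

Numerical details: the optimiser is BFGS with an analytic gradient,
started from the slope between the two groups bracketing 50% response,
followed by Newton polishing until the gradient norm is below 1e-10;
the fit is deterministic (no random restarts).  Identical dose levels
are pooled before fitting.  Patterns that are all-0% below some dose
and all-100% above it have no finite ML estimate (complete
separation); the fit then reports the midpoint of the bracketing doses
as `TD50`, flags `se_estimated`, and uses the fallback rule below.
Constant response patterns are rejected as unidentifiable.

### Fallback standard error

When no SE is available from the information matrix, it is estimated
as 25% of the dose difference between the neighbouring 0% and 100%
response levels.  If those levels overlap (non-monotone observed
rates), the adjacent dose pair bracketing 50% response is used
instead; a grid where no such pair exists raises an error rather than
guessing.

### Fieller confidence limits

`fieller_cl()` returns the exact normal-theory limits for a ratio of
two estimates with arbitrary covariance: the roots of
`(den² − z²se_den²)R² − 2(num·den − z²cov)R + (num² − z²se_num²)`.
When `g = (z·se_den/den)² ≥ 1` the denominator is not significantly
non-zero and the interval is unbounded; the function then returns an
explicit flag instead of numbers.  For small coefficients of variation
the limits coincide with the corresponding quantiles of the simulated
ratio distribution, which the tests confirm against 10^6 Monte-Carlo
draws.

## Linear-quadratic isoeffect analysis

Tolerance doses measured at different fraction numbers `n` are linked
by the LQ isoeffect condition: the per-fraction dose `d` solves
`d(1 + d/(α/β)) = BED50/n` and `TD50(n) = n·d` (the positive root of
the quadratic).  `fit_lq()` estimates `(BED50, α/β)` by weighted least
squares on the dose scale with known weights `1/SE²`, so that the
reported covariance is the error-propagation matrix `(JᵀWJ)⁻¹` at the
optimum — exact for two schedules, where the model interpolates.  The
dose scale (rather than the classical reciprocal-dose Fe-plot scale)
is used so the published TD50 standard errors act directly as weights;
the Fe-plot regression is retained as a starting-value heuristic and
as a cross-check (`method = "reciprocal"`).

Optimisation uses Levenberg–Marquardt (`minpack.lm`) with tight
tolerances (1e-14) and positivity bounds; noiseless synthetic
schedules are recovered to better than six significant digits.  90%
limits for `BED50` and `α/β` use the log-scale normal approximation,
which produces the asymmetric intervals expected for positive ratio
parameters.  `BED50` uncertainties are taken from the joint fit's
covariance rather than from propagation through a fixed `α/β`,
consistent with propagating the correlation of the underlying
parameters.

Fractionation sparing — `TD50` strictly increasing in `n` at fixed
`(BED50, α/β)` — is an analytic property of the model and is verified
numerically.  The model assumes complete repair between (daily)
fractions and no repopulation; incomplete-repair extensions are out of
scope.

## RBE ratios

`RBE = TD50_photon/TD50_ion` at equal fraction number, and
`RBE_max = BED50_photon/BED50_ion` in the low-dose limit.  Photon and
ion arms come from different cohorts and beams, so the cross-
covariance is zero; the within-arm correlations have already been
absorbed into each arm's SE.  First-order propagation gives
`se = RBE·sqrt(cv_num² + cv_den²)` and Fieller's theorem the 90%
limits.  A helper forms the model-side `RBE_max` as the ratio of LQ
α-values for benchmarking model tables.

The dose dependence is inter/extrapolated with the LQ model: for ion
dose per fraction `d_c`, the isoeffective photon dose solves
`d_x(1 + d_x/ab_x) = RBE_max · d_c (1 + d_c/ab_c)` and
`RBE(d_c) = d_x/d_c`.  The limits are `RBE_max` at `d_c → 0` and
`sqrt(RBE_max · ab_x/ab_c)` at `d_c → ∞`; in the high-LET regime
(`RBE_max` above the asymptote) the curve is strictly decreasing.

## Model benchmarking

Per-point deviations are `100·(RBE_model − RBE_exp)/RBE_exp`; the
experimental value is the denominator because the model is being
benchmarked against the measurement, and the sign convention makes an
underestimating model negative.  Region averages are the arithmetic
mean and sample SD (n−1) over the points of an LET region — by
default the entrance region {16, 21} keV/μm and the in-peak region
{36, 45, 66, 99} keV/μm — computed per fraction number, or per LET
across fraction numbers (`aggregate_over`).  Averaging the printed
per-schedule in-peak rows reproduces the published summary deviations
(−8.3% for the newer model version; −20.17% against a printed −20.1%
for the clinical one, the 0.07 gap being consistent with the source
having averaged unrounded row values).

The slope of RBE against LET over a region is, by default, a
straight-line least-squares fit, and the slope ratio
model/experiment carries a propagated SE.  Because the published
construction of this statistic is ambiguous, the derivative of the
order-2 polynomial at the region's mean LET and the endpoint
difference quotient are provided as alternatives
(`method = "poly_deriv"`, `"endpoint"`); none of the three is asserted
to reproduce the printed slope ratios.  The α/β-vs-LET trend is a
weighted linear regression.

## The synthetic cohort generator

`make_study_replica()` reproduces the design of the 6-fraction study:
a photon reference experiment plus six carbon experiments at LET 16,
21, 36, 45, 66 and 99 keV/μm with the study's dose grids, per-level
animal numbers (204 carbon + 30 photon animals; optionally 5 sham
controls), and a 300-day horizon.  The measured tolerance doses act as
generating truth.  Per experiment the logistic slope defaults to
`10 / (dose range)`, so each grid spans essentially 0–100% response —
matching how the dose levels were chosen in the study; for the
narrowest grid (99 keV/μm, 15–20 Gy) this gives a slope of 2 per Gy.
The photon dose grid (46–66 Gy) is a design choice of the generator,
as the photon reference curve predates the ion study.

Responder onset times are lognormal with `sigma_log = 0.25` and a
baseline median of 200 d, the log-median decreasing linearly in
LET/100 and in `D/TD50 − 1` with coefficient 0.3 — a right-skewed
model giving medians of roughly 150–250 d and a mild shortening with
LET and dose, as observed for this endpoint.  Onsets are truncated to
the horizon by resampling.  Non-responders are censored at the
horizon.  Each animal is independently lost to follow-up with
probability 0.02 (censored uniformly over the follow-up window and
flagged as excluded), emulating the sporadic intercurrent deaths of
the study, unless the endpoint had already occurred.

Each experiment draws from a private RNG stream seeded from the pair
(seed, experiment id), so adding experiments to a study never perturbs
existing ones, and the same seed reproduces byte-identical cohort
files.  The caller's RNG state is left untouched.

What the generator does *not* emulate: latency differences between
fraction numbers (all replica experiments are 6-Fx), inter-animal
heterogeneity of radiosensitivity beyond the binomial model,
dose-measurement uncertainty, and any volume or competing-risk
effects.  Recovery tests on these cohorts therefore validate the
estimation chain under its own assumptions — they cannot detect
model misspecification in real data.

## Problem sizes and test design

The validation suite uses: all 2- and 3-animal censoring
configurations against a brute-force product-limit oracle; 100 seeded
replicas of the study design for TD50/RBE recovery (coverage within
2 SE in at least 90 of 100); 100 seeded 30-animal experiments for CL
coverage (at least 85 of 100 inside the fit's own 90% interval); a
16-point grid over `(BED50, α/β) ∈ [25, 280]×[2.5, 45]` Gy with 2%
noise for LQ recovery within 3 SE; 10^6 Monte-Carlo draws for the
Fieller check; and groups of 10^4–10^5 simulated animals for the
law-of-large-numbers checks of the generator.  These sizes give
comfortable statistical margins for every asserted threshold while
keeping the whole suite fast.

## Known limitations

* The actuarial variance estimator of the original effective-sample-
  size method is not restated in the available sources; Greenwood's
  estimator is the default here, with the binomial form as an option.
* SEs of TD50 are delta-method SEs; profile-likelihood intervals are
  not implemented (Fieller limits cover the ratio structure, which is
  the dominant effect).
* The LQ stage assumes complete interfraction repair and no
  repopulation; it should not be applied to schedules with
  interfraction intervals much shorter than a day.
* `α/β` and `BED50` confidence limits use the log-normal
  approximation rather than a Fieller construction on the underlying
  α and β components, which are not separately identifiable from
  TD50-level summaries.
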