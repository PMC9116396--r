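---
title: "Methods: crossover mixed-effects analysis of force and subjective outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover mixed-effects analysis of force and subjective outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossforce)
```

## The problem

A double-blind, three-period crossover trial gives every participant all
three conditions — a caffeinated multi-ingredient supplement (C), its
non-caffeinated formulation (NC), and placebo (P) — in one of the six
possible orders. Outcomes are of two shapes: single-value measures per
participant × condition (isometric/isokinetic squat metrics derived from
load-cell traces, one-repetition maximums, repetitions to failure) and
repeated measures (0–100 visual-analog-scale ratings of energy, focus and
fatigue at five timepoints per visit). Crossover data of this kind need
adjustment for period effects (systematic drift across visits) and
carryover effects (residual influence of the previous period's condition),
and the repeated VAS series are serially correlated within a visit.

This package implements that full analysis as tested, reusable code, and —
because the original participant-level data are not public — ships a
seeded synthetic-data generator with known ground truth so every stage can
be validated by parameter recovery rather than by reproducing printed
coefficients.

## Force-signal processing

All trace analysis runs on a filtered signal: a low-pass Butterworth filter
with a 10-Hz cutoff applied forward and backward. The conventional
biomechanics label "fourth-order, zero-phase" is realised here as a
second-order design per pass, giving an effective fourth-order magnitude
response `1 / (1 + (f/fc)^4)` (exactly 1/2 at the cutoff) and zero net
phase; `order_per_pass` switches to a full fourth-order design per pass if
wanted. Two numerical choices matter at the edges of short (~3–4 s) pushes:

* **Padding.** The trace is extended by odd (point-reflected) padding of
  three times the impulse-response scale (`sample_rate / cutoff` samples)
  before filtering, suppressing startup transients; traces shorter than the
  pad are rejected with the minimum length in the error.
* **Initial state.** Each pass filters the deviation from the pass's
  starting value, so a constant trace passes through bit-exactly (DC gain
  1 within 1e-6 is asserted in the tests).

Onset of force production uses a relative threshold — 1% of the maximal
force — which is only meaningful on a zeroed signal: load cells read the
bodyweight preload, so the mean of the first 200 ms (configurable) is
subtracted first. A crossing must be sustained for 10 ms to count,
debouncing single-sample noise; both parameters are arguments.

Isometric peak force is the highest *mean* over any 500-ms window (stride
one sample, a true maximum rather than tiled epochs); the same moving-mean
machinery with a 25-ms window gives the per-phase isokinetic peaks, which
are averaged over repetitions 2 and 3 of the analysed set. The "highest
epoch" is read as the highest windowed mean (the 25-ms definition is
explicit about this; the 500-ms one is not, and we adopt the same reading).
Rate of force development over a window is the endpoint difference quotient
from onset; peak RFD is the maximum windowed slope between onset and the
force maximum, endpoint-based over 20 ms by default with a least-squares
variant by argument — the peak-RFD differentiation window is a genuine
reporting gap in the field, so it is explicit and configurable here.
Isokinetic phase boundaries come from the device command timeline (4-s
eccentric, ~1-s bottom pause, 4-s concentric, position-controlled device),
never inferred from force.

## The crossover model

For single-value outcomes:

```
value ~ condition + sex + condition:sex + visit + x1 + x2,  random = ~1 | participant
```

with reference levels placebo, female and visit 1. Carryover enters through
two indicators computed from the preceding period's condition: `x1 = 1` if
it was C, `x2 = 1` if it was NC; first-period rows and placebo-preceded
rows are both (0, 0), making placebo the carryover reference. Which
indicator flags which active condition is an arbitrary labelling (inference
is invariant to it); the choice is fixed and documented. Visit and
timepoint are categorical indicators so each level gets its own
coefficient.

Repeated VAS outcomes add `timepoint` and its two- and three-way
interactions with condition and sex, and an AR1 residual correlation within
each participant × condition series: adjacent timepoints correlate with
coefficient φ, decaying geometrically with lag.

Estimation is REML throughout. The independent-residual model is delegated
to `nlme::lme` (the standard backend for exactly this model family). The
AR1-within-group restricted likelihood is implemented directly: per
participant the covariance is `σ_b² J + σ_e² blockdiag(R(φ))` with `R` the
AR1 correlation; fixed effects and `σ_e²` are profiled out analytically and
the two remaining parameters (log variance ratio, atanh φ) are optimized by
Nelder–Mead from three starts. The direct implementation is cross-checked
in the tests against `nlme::lme` + `corAR1` as an independent oracle, and
the two routes agree at φ = 0.

When the numerical curvature of the restricted likelihood at the optimum is
not positive definite, interval estimates for the covariance parameters are
unobtainable; the model is then refit with independent residuals and the
result carries a `fallback` flag — mirroring the pragmatic fallback used in
practice when AR1 intervals cannot be produced.

**Inference scale.** Confidence intervals are Wald with normal critical
values (the reported intervals are symmetric 95% bands). p-values come from
the backend's t statistics for the nlme path; the direct AR1 fitter uses a
single within-group degrees-of-freedom approximation
(`N - n_participants - p + 1`), which at VAS scale (N = 360, p = 34) is
indistinguishable from normal. Satterthwaite/Kenward–Roger corrections are
out of scope. Whether the original intervals were Wald or profile is not
stated anywhere; Wald was chosen as the convention that matches symmetric
reported bands. Monte-Carlo calibration (acceptance tests) shows type-I
error within [3.5%, 6.5%] and CI coverage within [92%, 98%] at the trial's
n = 24.

**R².** Marginal R² is `var(Xβ) / (var(Xβ) + σ_b² + σ_e²)`; conditional R²
adds `σ_b²` to the numerator — the variance-partition definition for
random-intercept models.

## Transforms

Residual normality is screened by Shapiro–Wilk at α = 0.05. An outcome is
transformed only when normality is rejected *and* a candidate transform
improves the residual W statistic; candidates are the shifted log
(`log(x + offset)`, offset 0 for positive data, else
`|min| + max(1e-8, 1e-3 × range)`) and the ordered-quantile transform,
which maps mid-ranks to standard-normal quantiles at positions
`(r − 0.5)/n`. The plotting-position convention differs between reference
implementations; `(r − 0.5)/n` is the default and `r/(n + 1)` is available
by argument, with the choice recorded in the serialized transform record.
Both transforms are strictly monotone, so the sign of any condition effect
is preserved. The per-outcome preset used for the trial outcomes (log for
isometric peak force and early RFD, ordered-quantile for peak RFD) ships as
the pipeline default.

## Missing data

Invalid records (e.g. a repetitions-to-failure set performed at the wrong
load) are blanked, never deleted, and enumerated with reasons in the
missingness report. Missing outcomes are multiply imputed by
predictive-mean matching: within each outcome, a Bayesian linear model on
condition, sex, visit, timepoint and the participant's mean observed value
predicts every cell, and each missing cell takes the observed value of a
donor among the 5 nearest predictions. PMM keeps imputations on the
outcome's observed support, which suits bounded VAS scores; imputed VAS
values are additionally clamped to [0, 100]. The number of imputations
defaults to m = 100 ("100 iterations" is ambiguous between imputations and
within-chain iterations; we read it as m = 100 datasets, and a single
completed dataset is available by setting m = 1). Estimates are pooled by
Rubin's rules with Barnard–Rubin degrees of freedom for p-values.

One property deserves a caveat: pooled intervals exceed complete-data
intervals *in expectation* (the between-imputation variance is always
non-negative, and the tests assert both the strict within-variance ordering
and the mean ordering), but not in every single simulated dataset — at ~3%
missingness the residual-variance estimate shifts by a comparable amount
simply because different values occupy the missing cells.

## The synthetic-data generator

The generator is first-class, tested code and defines the study conditions:

* **Design.** 24 participants (12 per sex), six sequences used exactly
  four times (twice per sex), assignment order seeded per sex.
* **Traces.** Isometric pushes are a baseline (800 N preload), a logistic
  rise of amplitude 2000 N whose maximal slope is the target RFD
  (8000 N/s), and Gaussian noise (SD 5 N) at 1 kHz — the logistic shape
  makes peak-epoch mean, onset and every RFD metric available in closed
  form, so recovery is checked against analytic truth, with a
  piecewise-linear mode retained for exact-slope tests. Isokinetic sets are
  trapezoidal plateaus at commanded per-rep peaks on the 4/1/4-s timeline.
* **Trial tables.** Outcome values are grand mean + injected fixed effects
  (condition, sex, interaction, visit, carryover) + a participant intercept
  draw + residual; VAS outcomes add a five-timepoint profile, extra
  post-baseline condition effects, and stationary AR1(φ = 0.6) residual
  series, then clamp to [0, 100] (the clamping rate is reported so heavy
  clamping can be excluded from recovery studies). Default effect sizes and
  SDs are chosen to be physiologically plausible for recreationally trained
  adults (e.g. isometric peak force ~2500 N grand mean, ~1300 N male
  effect, participant SD 450 N) — they set realistic signal-to-noise, and
  every injected value is returned in the truth record.
* **Missingness.** Each VAS cell is missing independently with probability
  0.033, matching the trial's observed rate.

What the generator does *not* emulate: learning/fatigue structure beyond
additive visit effects, missingness that depends on the data (MCAR only),
floor/ceiling-censored force traces, or inter-outcome correlation beyond
the shared design. Passing recovery tests therefore demonstrates that the
estimation machinery is correct and calibrated under the declared model,
not that the model is true of any particular laboratory's data.

## Problem sizes and determinism

Monte-Carlo checks use 500 replicates for condition-effect recovery at 240
participants, 1000 for type-I error and 200 for AR1 recovery at the trial's
own n = 24, and 200 for imputation-pooling bias with m = 10 imputations —
sizes at which the Monte-Carlo standard error is well below each asserted
tolerance. Every random quantity flows from explicit integer seeds;
identical configurations produce bit-identical tables, traces and run
manifests, and the pipeline manifest enumerates every seed it consumed.

## Known limitations

* Degrees-of-freedom corrections for small samples (Satterthwaite,
  Kenward–Roger) are not implemented; at n = 24 the normal-critical-value
  CIs are very slightly liberal (coverage ~94–95% in simulation).
* The AR1 fallback approximates the reference behaviour ("default matrix")
  as independent residuals; other readings (e.g. compound symmetry) exist.
* PMM with small donor pools can be slightly under-dispersed at very high
  missingness; the trial's ~3% rate is far from that regime.
* The CLI is a thin wrapper over the package functions; orchestration
  beyond one run per config (caching, resume) is out of scope.
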