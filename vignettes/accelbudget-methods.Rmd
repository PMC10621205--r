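---
title: "Methods: from raw accelerometry to diel activity budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw accelerometry to diel activity budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelbudget)
```

# The problem

Small nocturnal mammals such as kangaroo rats (*Dipodomys*) are difficult to
observe directly, yet their behavior matters disproportionately: they are
keystone granivores and ecosystem engineers across arid western North
America. Miniaturized animal-borne accelerometers (~1.8 g loggers recording
tri-axial acceleration at 25 Hz over a ±10 g range for multi-day deployments)
make it possible to record behavior continuously. Turning those recordings
into science requires a chain of steps:

1. segment the acceleration stream into fixed windows and summarize each
   window with a battery of statistics;
2. train and select a supervised classifier against field-validated behavior
   labels (four classes: motionless, travel, foraging, grooming);
3. annotate whole deployments with predicted behavior;
4. assign every window to a solar light phase and a lunar state;
5. aggregate into activity budgets (proportion of time per behavior per
   individual, night and phase);
6. model those proportions against moonlight and weather with generalized
   linear mixed models (GLMMs).

This package implements the full chain, plus a synthetic-data generator with
known ground truth so that every stage can be validated end to end without
field data.

# Windows and features

Traces are tiled into non-overlapping windows (candidate sizes 1, 2, 3, 6 and
9 s) starting at the first sample; a trailing partial window is discarded.
Non-overlapping tiling avoids re-using samples between training and test
windows. Each window is summarized by 44 statistics: per-axis mean, standard
deviation, maximum, minimum and 25/50/75th percentiles; mean vector norm; the
three pairwise covariances and Pearson correlations; per-axis mean absolute
dynamic body acceleration (DBA) and the overall dynamic body acceleration
(ODBA); per-axis mean and standard deviation of first differences; per-axis
wave amplitude (max − min); and per-axis line crossings of the DBA sequence.
A named reduced set (per-axis mean, per-axis SD, ODBA) is also available.

Because the upstream web tool that inspired this battery does not publish its
formulas, the following conventions are fixed and documented here:

* moments use denominator *n* (population form);
* the static component removed for DBA is the window's own per-axis mean
  (windows are at most 9 s, so a separate running mean is unnecessary);
* ODBA is the *mean* (not sum) over samples of |DBAx| + |DBAy| + |DBAz|, so
  values are comparable across window sizes;
* percentiles use linear interpolation;
* line crossings count sign changes of the DBA sequence, with zeros
  inheriting the previous sign (leading zeros take the first nonzero sign);
* a Pearson correlation involving a zero-variance axis is defined as 0 and
  counted in a flag rather than propagating NaN into the classifiers.

Windows receive a behavior label only when their full span lies inside one
annotated bout, with 1 s of alignment slack at bout edges mirroring the
field protocol's "matched to within 1 s"; windows straddling a transition by
more than the slack stay unlabeled. If the slack makes a window compatible
with two adjacent bouts, the bout containing the window midpoint wins.

# Classifier protocol

Classes are balanced by subsampling every class, without replacement, to the
count of the rarest class. The balanced set is then split 50/50 into train
and test halves. The split is stratified by class — the protocol it mirrors
says only "random 50%", but stratification guarantees all four classes are
present on both sides at small sample sizes without changing the expected
split. Balancing happens before splitting, following the order of the
original protocol description.

Three algorithms are evaluated: a linear support vector machine (features
standardized with training-half statistics only), a decision tree, and a
random forest (library default hyperparameters, seeded). Every
(algorithm, feature set, window size) combination sees the same balanced
split. From each 4×4 confusion matrix (rows = true class) we compute
one-vs-rest per-class accuracy, precision TP/(TP+FP), recall TP/(TP+FN),
overall accuracy and unweighted macro averages. "Per-class accuracy" is
interpreted one-vs-rest; the source protocol does not disambiguate, and this
is the convention its printed per-class values are consistent with.

The selection score is the unweighted mean of macro accuracy, macro
precision and macro recall ("greatest average accuracy, precision, and
recall" leaves the aggregation open; the unweighted mean is the simplest
faithful reading). Ties break by macro recall, then smaller window (cheaper
annotation), then algorithm name — fully deterministic. The winning model
annotates whole deployments window by window, yielding a step-function
behavior time series.

# Ephemeris and light phases

No installed library provides solar/lunar ephemerides, so the package
computes them directly. Solar position uses the standard low-precision
century-polynomial series (mean longitude, mean anomaly, equation of center,
apparent longitude, corrected obliquity); the geometric altitude is accurate
to a few hundredths of a degree over 1900–2100. Lunar position uses a
truncated periodic-term expansion (16 longitude, 8 latitude, 4 distance
terms) plus a parallax-in-altitude correction, good to roughly 0.1°; the
illuminated fraction comes from the standard phase-angle polynomial in the
mean elongation and the solar/lunar anomalies, accurate to well under 0.02.
The test suite checks all three against an independently coded oracle of a
different algorithmic lineage and against published eclipse-anchored new/full
moon instants, where the truth is known to the minute.

The eight light phases are defined on the *geometric* (airless) solar
altitude, because the 0°/6°/18° bands follow astronomical convention:
`night` below −18°; `morning_twilight`/`evening_twilight` in [−18°, −6°)
split by whether the sun is rising or setting; `dawn`/`dusk` in [−6°, 0°)
likewise; above the horizon, `morning` is the first hour after sunrise,
`evening` the last hour before sunset, and `day` the rest. Altitude bands
are half-open with the lower altitude bound included, so −18° is twilight
and −6° is dawn/dusk — each instant maps to exactly one phase. Rising versus
setting is decided by the sign of the altitude change over ±30 s; boundary
instants are found by bisection to 1 s. Sunrise/sunset *times* for the
first/last-hour rules use the geometric 0° horizon for consistency with the
banding; a conventional −0.833° horizon (refraction plus semidiameter) is
available in `rise_set_times()` for reporting. Moon "up" means geometric
topocentric altitude above 0°, without a refraction correction — the
difference is minutes per night and irrelevant at the nightly grouping
scale. Latitudes beyond ±60° are rejected explicitly rather than guessing
through polar day/night.

A "night" is identified by the local calendar date of its preceding noon
(noon-to-noon grouping), so a continuous dark period is never split between
two identifiers; the source protocol groups by night but never defines the
cut. The nightly moonlight covariate is the illuminated fraction at local
solar midnight (the sun-altitude minimum between the bounding noons). Moon
intensity categories follow the published thresholds: below 0.33 low,
0.33–0.66 (inclusive on both ends) medium, above 0.66 high.

# Budgets

Each predicted window is assigned to the phase (and night, and moon-up
state) containing its *midpoint* — windows can straddle phase boundaries and
the midpoint is deterministic and unbiased. Counts and proportions of the
four behaviors are computed per grouping cell; proportions in a cell sum
to 1 and counts conserve the total number of classified windows, so
durations are exactly `n_windows × window_s`. Budgets are computed per
(individual, night, phase) and modeled with group sizes as weights rather
than pooled first, preserving the random-effect structure the GLMMs assume.
Whether the original analysis pooled nights is not stated; the per-night
resolution is finer and aggregates losslessly. The moonlight analysis is
restricted to phases with the sun below the horizon (dusk, evening twilight,
night, morning twilight, dawn). Precipitation nights can be flagged and
excluded via a configuration toggle.

# Mixed models

Budget proportions are modeled in a GLMM framework with random intercepts
for individual and night (dates are shared across individuals on the same
night) — random intercepts only, matching "ID and date as random factors".
Four candidate families are compared by AIC: gaussian (proportion response,
group-size weights), binomial (successes/trials), poisson (counts with a
log-trials offset) and gamma (proportion; infeasible when zeros are
present). One subtlety: likelihoods of a proportion and of the count it was
derived from live on different measurement scales, so their AICs are not
directly comparable. The package therefore maps proportion-scale likelihoods
to the count scale with the change-of-variables Jacobian
(`AIC + 2 Σ log n`), making the four candidates commensurable; the raw AIC
is retained as `AIC_raw`. With this correction, simulations from a known
binomial generator select binomial in ≥ 90% of replicates.

Fixed-effect significance uses Wald chi-square tests on each term's
coefficient block (`χ² = b'V⁻¹b`, df = block size). Model fit is summarized
by a Nakagawa-style conditional R²,
`(σ²_fixed + σ²_random) / (σ²_fixed + σ²_random + σ²_resid)`, with the
family-appropriate residual term on the link scale (residual variance for
gaussian, π²/3 for logit-binomial, `log(1 + 1/λ̄)` for log-poisson,
`trigamma(shape)` for log-gamma). Collinearity is screened with variance
inflation factors computed from the definition, `VIF_j = 1/(1 − R²_j)`, per
contrast column for categorical predictors; exact collinearity reports an
infinite VIF naming the offending columns. No multiple-testing adjustment is
applied across behaviors (the protocol applies none); Wald contrasts are
reported unadjusted.

Non-gaussian mixed fits use the Laplace approximation (lme4). If a mixed fit
fails outright, the model is refit as a fixed-effects GLM with
cluster-robust (by individual) standard errors and flagged `downgraded` — it
never silently changes family or drops the clustering structure.

# The synthetic generator

The generator defines the study conditions under which the pipeline is
validated; it is not a tuning knob.

**Behavior dynamics.** Bout sequences are sampled from a continuous-time
Markov chain over the four behaviors whose generator matrix switches with
the light phase. No generative behavioral model is published for this
system, so the CTMC is the simplest mechanism that produces phase-dependent
budgets with an analytically known truth (the per-phase stationary
distribution). The default profile encodes a strictly nocturnal animal:
during sun-up phases the stationary occupancy is ~99% motionless (travel
under 0.2%); dusk and evening twilight carry moderate activity; night,
morning twilight and dawn carry peak travel and foraging — late-night
activity exceeding early-night activity, as observed in the field. Phase
boundaries are sampled on a 60 s grid (phases change over minutes). Bouts
shorter than 2 s are absorbed into the preceding bout, because sub-2 s bouts
can be neither video-scored nor windowed. A per-night multiplier on the
rates *into* a behavior (e.g. foraging entry scaled by
`exp(β × humidity_std)`) is the hook used to inject covariate effects with
recorded ground truth.

**Signals.** Each behavior has a fixed gravity orientation (devices were
mounted in one orientation; no orientation drift is simulated), a sinusoidal
burst model (frequency, amplitude and phase drawn once per bout; bursts
gated by a duty cycle) and Gaussian noise. Travel oscillates at hop-like
4–8 Hz with 0.8–1.5 g amplitude dominated by the vertical axis. Foraging
(2–4 Hz, 0.25–0.6 g) and grooming (2.5–4.5 Hz, 0.2–0.5 g) share a single
head-down posture and deliberately overlapping parameter ranges: the two
classes are partially confusable by construction, reproducing the confusion
structure seen in real data, while both remain trivially separable from
motionless and travel. The overlap depth was calibrated once, at design
time, so that partial confusability persists even at the 9 s window size,
where windowed statistics are most precise and classes are easiest to
separate. Samples are clipped to the ±10 g sensor range and
clipping events are counted. Class-conditional ODBA means are ordered
motionless < grooming ≈ foraging < travel. No published quantitative
description of class-specific kangaroo-rat acceleration signatures exists;
these signal models are structural stand-ins, not estimates.

**Covariates.** Nightly temperature, wind and relative humidity are drawn
from configured seasonal means (defaults 28 °C ± 2, 3 m/s ± 1, 40 %RH ± 8 —
plausible summer values for a Chihuahuan desert grassland); moon
illumination comes from the ephemeris, so 30 consecutive nights sweep most
of the 0–1 range. A budget-level binomial simulator
(`simulate_budget_counts()`) generates window counts per (individual, night)
from a logit model with known slopes and random-intercept SDs; it is the
ground-truth channel used for calibration and power validation of the
modeling stage, because replicating the full 25 Hz pipeline hundreds of
times would add nothing but runtime to those checks.

**What the generator does not emulate.** Biomechanically realistic hop
kinematics, terrain and microhabitat effects, device-attachment artifacts,
orientation drift, sensor dropouts and clock drift are all out of scope.
Passing tests therefore demonstrate that the pipeline recovers truth under
its stated assumptions — not that a classifier trained on these synthetic
signatures would transfer to real loggers.

# Validation design and problem sizes

The test suite exercises, among others:

* feature-computation equivalence against a naive per-sample reference on
  1,000 random windows at 1e-9;
* classifier recovery on ≥ 300 windows per class before balancing across all
  five window sizes, requiring held-out overall accuracy ≥ 0.85 with the
  largest off-diagonal confusion cell being the foraging/grooming pair;
* bit-identical re-runs of the full pipeline (two animals × two nights,
  two window sizes, two algorithms) under a fixed seed;
* ephemeris agreement with the independent oracle over 1,000 random
  site-times (sun ≤ 0.5°, illumination ≤ 0.02, rise/set ≤ 5 min) plus
  eclipse-anchored almanac instants;
* light-phase totality and canonical ordering over a 48 h scan at 1 s;
* budget normalization (1e-9) and window-count conservation;
* Wald type-I error ≤ 0.08 at nominal 0.05 over 400 null replicates at the
  study-sized design (14 individuals × 20 nights), ≥ 80% power for the
  injected humidity→foraging effect at twice the study size, and the VIF
  closed form 1/(1 − 0.64) = 2.778 to 1e-3.

These sizes were chosen as the smallest designs that make the respective
statistical statements meaningful; `scripts/acceptance.R` recomputes the
same quantities from scratch with a caller-supplied seed.

# Known limitations

* The ephemeris is low-precision by design (sun ~0.01°, moon ~0.1°); it is
  ample for phase banding and nightly moonlight but not for astrometry.
* AIC comparability across families rests on the count-scale Jacobian
  mapping; other conventions exist and would reorder near-ties.
* The conditional R² uses the standard distribution-specific residual
  approximations for non-gaussian families; alternative observation-level
  variance definitions give somewhat different values.
* Polar and high-latitude sites (|lat| > 60°) are rejected rather than
  handled.
* Synthetic signal realism is structural, not biomechanical (see above), so
  classifier accuracies on synthetic data say nothing quantitative about
  accuracies on any real dataset.
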