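---
title: "Methods: stride-level fatigue analysis of trunk-mounted IMU data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride-level fatigue analysis of trunk-mounted IMU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Running-induced fatigue changes trunk biomechanics at the stride level:
vertical propulsion drops, mediolateral acceleration peaks and lumbar
rotational activity grow, impact loading becomes sharper, and
stride-to-stride dynamics become more variable and less regular. A single
lumbar-mounted inertial measurement unit (IMU) sampling tri-axial
acceleration (ax, ay, az) and angular velocity (gx, gy, gz) at 256 Hz
captures all of these signatures. `stridefatigue` implements the full
analysis chain from raw multichannel recordings — one non-fatigued (NF) and
one fatigued (F) run per participant — to statistical and machine-learning
summaries, together with a seeded synthetic cohort generator that provides
ground truth for every stage.

## Preprocessing and stride segmentation

Each of the six raw channels is low-pass filtered with a fourth-order
Butterworth filter (20 Hz cutoff). The filter is applied forward and
backward (zero phase) so that foot-strike timing is not lag-shifted; the
filter family states nothing about phase handling, and zero-phase
application is the standard choice when event timing matters downstream.
Edges are handled by odd-reflection padding long enough for the start-up
transient to decay inside the pad, which preserves DC exactly and keeps the
output the length of the input. The implemented two-pass magnitude response
is the squared single-pass Butterworth response; being a bilinear-transform
design it is exact at the prewarped cutoff and the tests evaluate it on the
warped frequency axis.

Two derived magnitude channels,
$a_{mag} = \sqrt{a_x^2 + a_y^2 + a_z^2}$ and
$g_{mag} = \sqrt{g_x^2 + g_y^2 + g_z^2}$, are computed from the filtered
raw channels, giving the fixed 8-channel order
(acc_x, acc_y, acc_z, acc_mag, gyro_x, gyro_y, gyro_z, gyro_mag).

Foot strikes are detected as local maxima of the filtered vertical
acceleration whose topographic prominence exceeds 0.5 times the channel's
standard deviation, with a minimum separation of 0.5 / (2 Hz) = 0.25 s
derived from a plausible cadence band; both thresholds are configurable
because no canonical values exist. A stride is the half-open interval
between consecutive detected events — one-interval windows used
consistently, which keeps strides disjoint and exhaustive between the first
and last event. Each window is resampled to N = 128 points (a power of two,
convenient for the FFT) by linear interpolation on the normalized time
grid; windows shorter than 4 source samples are dropped with a warning
rather than aborting a cohort run.

## Per-stride features

For every channel of every normalized stride the package computes the
population-moment statistics mean, standard deviation, RMS, min, max,
skewness, non-excess kurtosis (Gaussian $\to$ 3) and energy
$\sum_t x(t)^2$ — 8 statistics x 8 channels = the 64-column base feature
matrix. Zero-variance strides return skewness = kurtosis = 0 with a
degenerate flag instead of an error.

Spectral features use the one-sided FFT power spectrum with the DC bin
excluded, so a large mean cannot masquerade as periodicity: dominant
frequency (argmax bin), spectral entropy $-\sum_k p_k \ln p_k$ of the
normalized power distribution (natural logarithm, unnormalized), and
bandpowers over configurable half-open bands, default [0.5, 3), [3, 8) and
[8, 20) Hz (locomotor, impact, high-frequency). Because strides are
time-normalized, the frequency axis of stride *i* uses its effective
sampling rate $N / T_i$, preserving physical Hz.

Sample entropy follows the template-matching formulation
$\mathrm{SampEn}(m, r) = -\ln(A/B)$, where *B* counts ordered template
pairs of length *m* within Chebyshev tolerance $r\sigma$ and *A* the
analogous count at length $m + 1$, both over the $n - m$ templates that
admit an extension. Defaults are the field-standard m = 2 and r = 0.2
(as a fraction of the series' population SD). A constant series yields 0
(all templates match); absent matches yield an explicit incomputable
sentinel (`NA` with an attribute), never a silent infinity. The
implementation is verified against an independent brute-force pair counter
on all series lengths up to 30.

## Mixed-effects fatigue effects and standardized effect sizes

For each feature $y$ the package fits, by REML via `lme4`,

$$y_{ij} = \beta_0 + \beta_1\,\mathrm{Fatigue}_{ij} + u_{0j} +
\varepsilon_{ij}, \qquad u_{0j} \sim N(0, \sigma_u^2),\;
\varepsilon_{ij} \sim N(0, \sigma^2),$$

with participant-specific random intercepts absorbing between-runner
baselines and unequal stride counts. From the fit it derives:

* Cohen's $d = |\hat\beta_1| / \sigma$, reported as a magnitude (the
  reference tables print positive *d* for negative coefficients);
* marginal and conditional $R^2$ in the Nakagawa–Schielzeth form, with
  $\sigma_f^2$ the variance of the fixed-effect linear predictor over the
  observed design;
* partial $R^2 = z^2 / (z^2 + df)$ from the Wald statistic of the fatigue
  term.

The effective residual degrees of freedom in the partial $R^2$ are set to
the total number of strides in the model. This choice reproduces the
published worked values 0.310, 0.207 and 0.120 at three decimals and is
insensitive to perturbations of tens of degrees of freedom; it is
configurable. One published row (lateral acceleration peak) prints 0.158
where this formula gives 0.159 with the printed z — a rounding-level
discrepancy in the source that the package documents rather than forces.

## Global and personalized models

Population-level classifiers (random forest with 300 trees, RBF SVM with
C = 1 and a median-distance bandwidth heuristic, gradient boosting with
200 stages at learning rate 0.1 — none of these hyperparameters has a
published value, all are seeded and configurable) are evaluated under
strict leave-one-participant-out (LOPO) cross-validation: one fold per
participant, feature standardization computed from the training
participants only, and the reported aggregate is the arithmetic mean of
per-participant metrics, never stride-pooled accuracy. An optional shallow
1D-CNN stage on the raw N x 8 stride tensors requires a deep-learning
backend; when none is installed the stage disables itself cleanly and the
pipeline proceeds.

Personalized models come in two forms. The supervised variant trains a
random forest on one runner's own strides under stratified K-fold
cross-validation (K = 5 by default; K is reduced with a warning, floor 2,
when a class is small). The anomaly variant fits a one-class SVM (RBF, nu
= 0.1, bandwidth 1/p on standardized features) on the participant's NF
strides only — fatigue is then detected as deviation from the personal
baseline. Standardization uses NF-only statistics carried inside the
model, so fatigued rows can never influence the fit. The binary view uses
the fitted boundary's native zero level as threshold; the rank AUC of the
continuous decision score (oriented so more anomalous = more fatigue-like)
is reported alongside recall on F and false-positive rate on NF.

Both model families consume the base 64-feature matrix by default, with
the spectral/entropy extension selectable via configuration; the published
feature-importance table lists only moment/energy names, so the base-64
interpretation is the default.

## Stride-to-stride variability

For each participant x state x feature, the stride-ordered trajectory of a
per-stride feature is summarized by its mean, population variance,
coefficient of variation $CV = \sigma_f / \mu_f$, and trajectory SampEn
(same m = 2, r = 0.2 defaults as the stride level). Trajectories never
cross the NF/F boundary, and the state deltas are exact F-minus-NF
subtractions, so swapping state labels negates them.

## The synthetic cohort generator

The generator is the test bed for every stage, so its mechanics matter.
Per channel a stride is a sum of three harmonics of the stride frequency
(~1.3 Hz, with between-participant spread); the vertical channel adds a DC
offset and one Gaussian impact pulse per stride at foot strike. Per
participant a random intercept (SD 0.5 by default) shifts all channel DC
levels, and fatigue is injected as:

* a vertical DC drop (default -0.8), sized after the published vertical
  fixed effect;
* a lateral first-harmonic increase (+0.5), raising lateral peaks;
* impact sharpening by 1.5 with the pulse area preserved (amplitude x 1.5,
  width / 1.5) — this keeps the vertical mean shift exactly the configured
  delta while kurtosis rises;
* inflation (x 2) of the white measurement noise and of the white
  per-stride amplitude jitter, and inflation (x 1.5) of the stride-period
  jitter.

The impact width is specified in seconds (a ground-contact property) and
converted to a phase width per stride, so period jitter propagates into
feature variability. Stride-to-stride amplitude variation has two
components: a slow sinusoidal pacing modulation (SD 0.08, period ~20
strides, random phase; identical in both states) and white per-stride
jitter (SD 0.04, inflated under fatigue). The decomposition is deliberate:
trajectory SampEn with r proportional to the trajectory SD is
scale-invariant, so merely inflating variance cannot raise it — only
replacing predictable structure with unpredictable variation can. The
pacing oscillation gives NF trajectories a genuinely low SampEn that the
fatigue-inflated white jitter then erodes, which is how the generator
realizes both the CV and the irregularity directions at once. Gyroscope
noise defaults to SD 8 (deg/s-like) so that its fatigue inflation
survives the 20 Hz low-pass and remains visible in rotational RMS.

Units are arbitrary m/s2-like and deg/s-like scales; the generator aims at
the documented effect directions and plausible magnitudes, not at
physiological realism. What it does **not** emulate: gait asymmetry and
step-versus-stride substructure, non-stationary fatigue onset within a
run, sensor drift or orientation change, heavy-tailed impact noise, and
any real coupling between channels beyond shared amplitude modulation.
Passing tests on this cohort therefore demonstrate correctness of the
pipeline's computations and recovery of configured effects — not claims
about real runners.

## Numerical choices and degenerate inputs

* A fixed seed plus fixed configuration gives bit-identical cohorts and
  byte-identical pipeline outputs; each stage derives its randomness from
  the single configured seed.
* Constant series: moments are exact, skew/kurt are 0 with a degenerate
  flag, SampEn is 0, the spectral stage flags a flat spectrum (dominant
  frequency `NA`, entropy 0), and the peak detector flags the recording
  as not segmentable.
* A trajectory with zero mean has an undefined CV (`NA` sentinel).
* Half-open stride windows make segmentation exhaustive and disjoint;
  window endpoints map to phases 0 and (N-1)/N.
* Single-class training folds are skipped with a warning; per-feature
  mixed-model failures are isolated and reported while the remaining
  features are processed.

## Problem sizes used in the shipped checks

The test-suite cohorts are scaled versions of the default study shape
(19 participants, 50-80 strides per 400 m run per condition): direction
and recovery checks use 4-12 participants with 20-26 strides per
condition, mixed-model calibration uses 20 participants x 200 strides
simulated directly from the random-intercept model (its independent
oracle), and the variability invariant pools two 12-participant cohorts.
These sizes were chosen as the smallest at which the checked effects are
comfortably larger than their Monte-Carlo error.

## Known limitations

* With few baseline strides and the full 64-dimensional feature set, the
  one-class SVM's empirical false-positive rate on NF strides can exceed
  nu noticeably (a small-sample, high-dimension effect); the nu contract
  is recovered at larger baseline counts or lower feature dimension.
* Wald confidence intervals and p-values are normal approximations, as in
  the reference tables; no degrees-of-freedom correction is applied.
* The stride granularity is one detected-event interval; no
  initial-contact/toe-off sub-events, orientation estimation or
  magnetometer processing is attempted.
* No multiple-testing correction is applied across features, matching the
  reference analysis.
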