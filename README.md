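# stridefatigue

Stride-level fatigue analysis of trunk-mounted IMU running data.

A single lumbar-mounted inertial measurement unit (IMU) recording
tri-axial acceleration and angular velocity at 256 Hz carries rich
signatures of running-induced fatigue: reduced vertical propulsion,
larger mediolateral peaks, sharper impact loading, more rotational
activity, and more irregular stride-to-stride dynamics. `stridefatigue`
turns raw recordings — one non-fatigued (NF) and one fatigued (F) run per
participant — into statistical and machine-learning summaries of those
signatures, and ships a seeded synthetic cohort generator with known
ground truth so the whole chain is testable without any external data.

The pipeline:

1. **Preprocess & segment** — zero-phase 4th-order Butterworth low-pass
   (20 Hz), derived magnitude channels
   `amag = sqrt(ax² + ay² + az²)`, `gmag = sqrt(gx² + gy² + gz²)`,
   foot-strike detection by prominence-thresholded peaks in vertical
   acceleration, and time-normalization of every stride to N = 128
   samples × 8 channels.
2. **Features** — per stride and channel: mean, std, RMS, min, max,
   skewness, kurtosis, energy (the 64-column base matrix), plus dominant
   frequency, spectral entropy `−Σ pₖ ln pₖ`, bandpowers, and sample
   entropy `SampEn(m, r) = −ln(A/B)`.
3. **Mixed-effects inference** — per feature, a random-intercept model
   `y_ij = β₀ + β₁·Fatigue_ij + u_0j + ε_ij` (REML via lme4) with
   standardized effect sizes: Cohen's `d = |β₁|/σ`, Nakagawa–Schielzeth
   marginal/conditional R², and partial `R² = z²/(z² + df)`.
4. **Global models** — RF / RBF-SVM / gradient boosting under strict
   leave-one-participant-out (LOPO) cross-validation, leakage-free
   fold-wise standardization, per-participant metrics.
5. **Personalized models** — per-runner supervised random forests
   (stratified K-fold) and NF-only one-class SVM anomaly detection
   (fatigue as deviation from the personal baseline).
6. **Variability** — stride-to-stride trajectory mean, variance,
   CV = σ/μ and trajectory SampEn per participant × state, with exact
   F − NF deltas.

## Worked example

```r
library(stridefatigue)

cfg <- pipeline_config(list(
  synth = list(n_participants = 6, strides_per_condition = 40),
  feature_set = "base", models = "rf",
  seed = 42, out_dir = "demo-out"))
run_pipeline(cfg)
#> simulate: wrote 12 recordings
#> segment: 468 foot strikes detected, 456 stride windows written
#> features: 456 strides x 64 features
#> effects: 4 features fitted, 0 failed
#> global-eval [rf]: 6 folds, mean accuracy 1.0000
#> personal-eval: 6 participants, 0 anomaly model(s) skipped

effects <- read.csv("demo-out/effects.csv")
effects[, c("feature", "beta", "se", "z", "d", "r2_partial")]
#>        feature   beta      se       z    d r2_partial
#> 1 acc_mag_kurt  3.679 0.04038   91.13 8.54     0.9479
#> 2   acc_z_mean -0.813 0.00799 -101.85 9.54     0.9579
#> 3    acc_y_max  0.523 0.01586   32.99 3.09     0.7048
#> 4   gyro_y_rms  0.445 0.24462    1.82 0.17     0.0072
```

Reading the output: the synthetic cohort injects a vertical-mean drop of
−0.8, and the mixed model recovers `beta = −0.813` for `acc_z_mean` with a
Wald z of −101.9; impact kurtosis and lateral peaks rise as configured.
Effect sizes are huge here because the synthetic strides are far cleaner
than real ones — with only six homogeneous runners the global LOPO model
also separates perfectly, unlike real cohorts where between-runner
heterogeneity dominates (raise `random_intercept_sd` and shrink the
fatigue deltas to reproduce that regime). Every stage writes its tables
(`features.csv`, `effects.csv`, `forest.csv`, `lopo_*.csv`,
`personal_*.csv`, `variability*.csv`) plus the resolved `config.yaml` into
the output directory, and identical seeds give byte-identical outputs.

A thin command-line wrapper with the same stages lives at
`inst/cli/stride-fatigue.R`:

```sh
Rscript inst/cli/stride-fatigue.R --config cfg.yaml --stages simulate,segment,features
```

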