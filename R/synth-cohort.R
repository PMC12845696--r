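#' Configuration for a synthetic running cohort
#'
#' Defines the generative model for a seeded synthetic IMU running cohort
#' with known ground-truth fatigue effects. Each participant contributes one
#' non-fatigued (NF) and one fatigued (F) recording. Per channel, the signal
#' is a sum of 3 harmonics of the stride frequency; the vertical acceleration
#' channel additionally carries a DC offset and one Gaussian-shaped impact
#' pulse per stride at foot strike. Fatigue is injected as a drop in the
#' vertical DC level, a raised lateral first-harmonic amplitude (higher
#' lateral peaks), a sharpened impact pulse (higher kurtosis), and inflated
#' amplitude noise and stride-period jitter (higher RMS/irregularity).
#'
#' Units are arbitrary acceleration-like (m/s^2 scale) and angular-velocity-
#' like (deg/s scale); effect directions, not physiological realism, are the
#' design target.
#'
#' @param n_participants Number of participants (default 19).
#' @param strides_per_condition Either a single count or a length-2 range
#'   from which a per-participant stride count is drawn (default 50--80,
#'   emulating a 400 m run).
#' @param sampling_rate Sampling rate in Hz (default 256).
#' @param stride_frequency_mean Mean stride frequency in Hz (default 1.3).
#' @param stride_frequency_sd Between-participant SD of stride frequency.
#' @param dc_levels Named numeric vector of per-channel DC offsets
#'   (channels ax, ay, az, gx, gy, gz).
#' @param harmonic_amplitudes Named list of per-channel harmonic amplitude
#'   vectors (harmonic k multiplies sin(2*pi*k*phase + psi_k)).
#' @param impact_amplitude Amplitude of the vertical impact pulse.
#' @param impact_width Impact pulse width (Gaussian SD) in seconds.
#' @param noise_sd Named numeric vector of per-channel white-noise SDs.
#' @param timing_jitter_sd SD of per-stride period jitter, as a fraction of
#'   the stride period.
#' @param amplitude_jitter_sd SD of the white (stride-to-stride independent)
#'   multiplicative amplitude jitter applied to the harmonic and impact
#'   components (not the DC level), as a fraction of their nominal scale;
#'   inflated under fatigue together with the measurement noise, this
#'   drives both the coefficient of variation and the irregularity
#'   (trajectory SampEn) of stride-to-stride feature sequences.
#' @param amplitude_drift_sd SD of the slow pacing modulation of the
#'   amplitude (a sinusoid over strides with random phase and a period of
#'   roughly \code{amplitude_drift_period} strides), identical in both
#'   states; it emulates the slow pacing oscillation of a steady run,
#'   giving non-fatigued stride-feature trajectories a predictable
#'   (low-SampEn) structure that the fatigue-inflated white jitter then
#'   disrupts.
#' @param amplitude_drift_period Mean period of the pacing modulation in
#'   strides (default 20); the realized period is drawn per recording
#'   within +/-25\%.
#' @param fatigue_effects List with elements \code{delta_vertical_mean}
#'   (signed shift of the vertical DC level), \code{delta_lateral_peak}
#'   (signed increment of the lateral first-harmonic amplitude),
#'   \code{impact_sharpen_factor} (> 0, divides the impact width),
#'   \code{noise_inflation} and \code{jitter_inflation} (>= 1 multipliers).
#' @param random_intercept_sd SD of the per-participant random intercept
#'   added to all channel DC levels.
#' @param seed Integer seed; a fixed seed and configuration give
#'   bit-identical cohorts.
#'
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_participants = 19,
                         strides_per_condition = c(50, 80),
                         sampling_rate = 256,
                         stride_frequency_mean = 1.3,
                         stride_frequency_sd = 0.08,
                         dc_levels = c(ax = 0.3, ay = 0.2, az = 2.2,
                                       gx = 1.0, gy = 2.0, gz = 0.5),
                         harmonic_amplitudes = list(
                           ax = c(0.6, 0.30, 0.15),
                           ay = c(0.8, 0.40, 0.20),
                           az = c(1.0, 0.50, 0.25),
                           gx = c(20, 10, 5),
                           gy = c(30, 15, 7),
                           gz = c(15, 8, 4)),
                         impact_amplitude = 8,
                         impact_width = 0.03,
                         noise_sd = c(ax = 0.15, ay = 0.15, az = 0.15,
                                      gx = 8, gy = 8, gz = 8),
                         timing_jitter_sd = 0.03,
                         amplitude_jitter_sd = 0.04,
                         amplitude_drift_sd = 0.08,
                         amplitude_drift_period = 20,
                         fatigue_effects = list(
                           delta_vertical_mean = -0.8,
                           delta_lateral_peak = 0.5,
                           impact_sharpen_factor = 1.5,
                           noise_inflation = 2,
                           jitter_inflation = 1.5),
                         random_intercept_sd = 0.5,
                         seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              strides_per_condition = as.integer(strides_per_condition),
              sampling_rate = sampling_rate,
              stride_frequency_mean = stride_frequency_mean,
              stride_frequency_sd = stride_frequency_sd,
              dc_levels = dc_levels,
              harmonic_amplitudes = harmonic_amplitudes,
              impact_amplitude = impact_amplitude,
              impact_width = impact_width,
              noise_sd = noise_sd,
              timing_jitter_sd = timing_jitter_sd,
              amplitude_jitter_sd = amplitude_jitter_sd,
              amplitude_drift_sd = amplitude_drift_sd,
              amplitude_drift_period = amplitude_drift_period,
              fatigue_effects = fatigue_effects,
              random_intercept_sd = random_intercept_sd,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

raw_channel_names <- function() c("ax", "ay", "az", "gx", "gy", "gz")

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1L,
            all(cfg$strides_per_condition >= 1L),
            length(cfg$strides_per_condition) %in% 1:2,
            cfg$sampling_rate > 0,
            cfg$stride_frequency_mean > 0,
            cfg$timing_jitter_sd >= 0,
            cfg$amplitude_jitter_sd >= 0,
            cfg$amplitude_drift_sd >= 0,
            cfg$amplitude_drift_period > 1,
            cfg$random_intercept_sd >= 0)
  chans <- raw_channel_names()
  if (!all(chans %in% names(cfg$dc_levels)))
    stop("dc_levels must name all channels ", paste(chans, collapse = ", "))
  if (!all(chans %in% names(cfg$harmonic_amplitudes)))
    stop("harmonic_amplitudes must name all channels")
  if (!all(chans %in% names(cfg$noise_sd)))
    stop("noise_sd must name all channels")
  fe <- cfg$fatigue_effects
  req <- c("delta_vertical_mean", "delta_lateral_peak",
           "impact_sharpen_factor", "noise_inflation", "jitter_inflation")
  if (!all(req %in% names(fe)))
    stop("fatigue_effects must contain: ", paste(req, collapse = ", "))
  stopifnot(fe$impact_sharpen_factor > 0,
            fe$noise_inflation >= 1, fe$jitter_inflation >= 1)
  # the sampling rate must resolve the highest harmonic of the fastest stride
  n_harm <- max(vapply(cfg$harmonic_amplitudes, length, 1L))
  f_max <- (cfg$stride_frequency_mean + 4 * cfg$stride_frequency_sd) * n_harm
  if (cfg$sampling_rate <= 2 * f_max)
    stop("sampling_rate must exceed twice the highest harmonic frequency")
  invisible(cfg)
}

#' Evaluate the noiseless stride waveform on a phase grid
#'
#' Deterministic signal model for one stride: per channel a DC offset plus a
#' harmonic sum of the stride frequency; the vertical channel (az) carries an
#' additional Gaussian impact pulse centred at phase 0 (wrapping at phase 1).
#' Magnitude channels are not produced here; they are derived downstream
#' from the raw channels.
#'
#' @param phase_grid Sorted numeric vector of stride-phase fractions in
#'   [0, 1).
#' @param params List with elements \code{dc} (named vector),
#'   \code{harmonics} (named list of amplitude vectors),
#'   \code{impact_amplitude} and \code{impact_width_phase} (pulse SD as a
#'   fraction of the stride period).
#' @return Numeric matrix, \code{length(phase_grid)} rows by 6 channels
#'   (ax, ay, az, gx, gy, gz).
#' @export
generate_stride_waveform <- function(phase_grid, params) {
  if (is.unsorted(phase_grid) || any(phase_grid < 0 | phase_grid >= 1))
    stop("phase_grid must be sorted and within [0, 1)")
  unlisted <- unlist(params[c("dc", "harmonics", "impact_amplitude",
                              "impact_width_phase")], use.names = FALSE)
  if (any(!is.finite(unlisted)))
    stop("non-finite waveform parameters")
  chans <- raw_channel_names()
  out <- matrix(0, nrow = length(phase_grid), ncol = length(chans),
                dimnames = list(NULL, chans))
  for (ch in chans) {
    amp <- params$harmonics[[ch]]
    y <- rep(params$dc[[ch]], length(phase_grid))
    for (k in seq_along(amp)) {
      # fixed per-harmonic phase offsets decorrelate the channels
      psi <- 0.7 * k + 0.4 * match(ch, chans)
      y <- y + amp[k] * sin(2 * pi * k * phase_grid + psi)
    }
    out[, ch] <- y
  }
  if (params$impact_amplitude != 0) {
    d <- pmin(phase_grid, 1 - phase_grid)  # wrap distance to foot strike
    w <- params$impact_width_phase
    out[, "az"] <- out[, "az"] + params$impact_amplitude * exp(-0.5 * (d / w)^2)
  }
  out
}

# Waveform parameters for one participant under one condition.
# Fatigue deltas are applied here, so NF and F share the participant's
# baseline parameters (including the random intercept).
participant_waveform_params <- function(cfg, intercept, condition) {
  dc <- cfg$dc_levels + intercept
  harm <- cfg$harmonic_amplitudes
  impact_width <- cfg$impact_width  # seconds; converted per stride
  impact_amplitude <- cfg$impact_amplitude
  if (condition == "F") {
    fe <- cfg$fatigue_effects
    dc[["az"]] <- dc[["az"]] + fe$delta_vertical_mean
    harm$ay[1] <- harm$ay[1] + fe$delta_lateral_peak
    # sharpen the impact preserving the pulse area, so the vertical mean
    # shift stays exactly delta_vertical_mean while kurtosis increases
    impact_width <- impact_width / fe$impact_sharpen_factor
    impact_amplitude <- impact_amplitude * fe$impact_sharpen_factor
  }
  list(dc = dc, harmonics = harm,
       impact_amplitude = impact_amplitude,
       impact_width = impact_width)
}

#' Generate one synthetic recording with ground truth
#'
#' Concatenates \code{n_strides} stride waveforms whose periods are jittered
#' around the participant's stride period, adds white noise, and (for the
#' fatigued condition) applies the configured fatigue effects including
#' inflated jitter and noise. Uses the current R random-number state.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @param participant_id Identifier stored in the recording.
#' @param intercept Participant random intercept added to all DC levels.
#' @param stride_frequency Participant stride frequency in Hz.
#' @param condition "NF" or "F".
#' @param n_strides Number of strides (>= 2).
#' @return List with elements \code{recording} (a \code{raw_recording}) and
#'   \code{ground_truth} (data frame of true foot-strike times and 1-based
#'   sample indices; \code{n_strides + 1} window boundaries).
#' @export
generate_recording <- function(cfg, participant_id, intercept,
                               stride_frequency, condition, n_strides) {
  condition <- match.arg(condition, c("NF", "F"))
  if (n_strides < 2) stop("n_strides must be >= 2")
  params <- participant_waveform_params(cfg, intercept, condition)
  jitter_sd <- cfg$timing_jitter_sd
  amp_jitter_sd <- cfg$amplitude_jitter_sd
  noise_sd <- cfg$noise_sd
  if (condition == "F") {
    jitter_sd <- jitter_sd * cfg$fatigue_effects$jitter_inflation
    amp_jitter_sd <- amp_jitter_sd * cfg$fatigue_effects$noise_inflation
    noise_sd <- noise_sd * cfg$fatigue_effects$noise_inflation
  }
  fs <- cfg$sampling_rate
  t0 <- 1 / stride_frequency
  periods <- t0 * pmax(0.5, 1 + stats::rnorm(n_strides, 0, jitter_sd))
  # slow pacing modulation (shared structure across states) plus white
  # jitter (inflated under fatigue): fatigue raises both the spread and
  # the unpredictability of the stride-to-stride amplitude sequence
  drift <- if (cfg$amplitude_drift_sd > 0) {
    period <- cfg$amplitude_drift_period * stats::runif(1, 0.75, 1.25)
    phase0 <- stats::runif(1, 0, 2 * pi)
    cfg$amplitude_drift_sd * sqrt(2) *
      sin(2 * pi * seq_len(n_strides) / period + phase0)
  } else numeric(n_strides)
  amp_scale <- 1 + drift + stats::rnorm(n_strides, 0, amp_jitter_sd)
  n_samp <- pmax(4L, as.integer(round(periods * fs)))
  blocks <- vector("list", n_strides)
  for (s in seq_len(n_strides)) {
    phases <- (seq_len(n_samp[s]) - 1) / n_samp[s]
    # amplitude jitter scales the dynamic components, not the DC level;
    # the impact width is fixed in seconds (a ground-contact property), so
    # its phase width varies with the jittered stride period
    params_s <- params
    params_s$harmonics <- lapply(params$harmonics, `*`, amp_scale[s])
    params_s$impact_amplitude <- params$impact_amplitude * amp_scale[s]
    params_s$impact_width_phase <- params$impact_width / periods[s]
    blocks[[s]] <- generate_stride_waveform(phases, params_s)
  }
  x <- do.call(rbind, blocks)
  total <- nrow(x)
  for (ch in colnames(x)) {
    if (noise_sd[[ch]] > 0)
      x[, ch] <- x[, ch] + stats::rnorm(total, 0, noise_sd[[ch]])
  }
  starts <- cumsum(c(0L, n_samp))            # n_strides + 1 boundaries
  data <- data.frame(time = (seq_len(total) - 1) / fs)
  for (ch in colnames(x)) data[[ch]] <- x[, ch]
  rec <- raw_recording(participant_id, condition, fs, data)
  gt <- data.frame(participant = participant_id, condition = condition,
                   event_index = starts + 1L, event_time = starts / fs)
  list(recording = rec, ground_truth = gt)
}

#' Generate a full synthetic cohort
#'
#' Draws per-participant random intercepts and stride frequencies, then
#' generates exactly one NF and one F recording per participant. All
#' randomness flows from \code{cfg$seed}, so a fixed configuration yields a
#' bit-identical cohort.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @return Object of class \code{stride_cohort}: list with
#'   \code{recordings} (list of \code{raw_recording}), \code{ground_truth}
#'   (combined event data frame), \code{participants} (data frame of drawn
#'   intercepts, stride frequencies and stride counts) and \code{config}.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  np <- cfg$n_participants
  intercepts <- stats::rnorm(np, 0, cfg$random_intercept_sd)
  freqs <- pmax(0.5, stats::rnorm(np, cfg$stride_frequency_mean,
                                  cfg$stride_frequency_sd))
  spc <- cfg$strides_per_condition
  counts <- if (length(spc) == 2L) {
    spc[1] + floor(stats::runif(np) * (spc[2] - spc[1] + 1L))
  } else rep(spc, np)
  recordings <- list()
  gt <- list()
  for (j in seq_len(np)) {
    pid <- sprintf("P%02d", j)
    for (cond in c("NF", "F")) {
      out <- generate_recording(cfg, pid, intercepts[j], freqs[j],
                                cond, counts[j])
      recordings[[paste(pid, cond, sep = "_")]] <- out$recording
      gt[[paste(pid, cond, sep = "_")]] <- out$ground_truth
    }
  }
  structure(list(recordings = recordings,
                 ground_truth = do.call(rbind, c(gt, make.row.names = FALSE)),
                 participants = data.frame(
                   participant = sprintf("P%02d", seq_len(np)),
                   intercept = intercepts, stride_frequency = freqs,
                   n_strides = as.integer(counts)),
                 config = cfg),
            class = "stride_cohort")
}

#' @export
print.stride_cohort <- function(x, ...) {
  cat("Synthetic stride cohort:", x$config$n_participants,
      "participants,", length(x$recordings), "recordings\n")
  invisible(x)
}
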