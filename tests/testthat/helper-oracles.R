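# Independent brute-force sample entropy: explicit double loop over ordered
# template pairs, kept deliberately separate from the package implementation.
sampen_bruteforce <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  sigma <- sqrt(mean((x - mean(x))^2))
  if (sigma == 0) return(0)
  tol <- r_frac * sigma
  count_pairs <- function(len) {
    nt <- n - m
    cnt <- 0L
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (i == j) next
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= tol)
          cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

# Simulate a stride-level response directly from the random-intercept
# generative model: y_ij = b0 + b1 * fatigue + u_j + e_ij.
simulate_lmm_cohort <- function(n_participants, strides_per_condition,
                                beta0 = 0, beta1 = 1,
                                sigma_u = 1, sigma_e = 1, seed = 1L) {
  set.seed(seed)
  u <- rnorm(n_participants, 0, sigma_u)
  rows <- lapply(seq_len(n_participants), function(j) {
    fatigue <- rep(c(0L, 1L), each = strides_per_condition)
    data.frame(participant = sprintf("P%02d", j),
               condition = fatigue,
               stride_index = seq_along(fatigue),
               y = beta0 + beta1 * fatigue + u[j] +
                 rnorm(length(fatigue), 0, sigma_e))
  })
  do.call(rbind, rows)
}

imu_channels <- c("ax", "ay", "az", "gx", "gy", "gz")

# Run a cohort through the in-memory preprocessing chain:
# filter -> magnitudes -> foot strikes -> normalized windows -> features.
cohort_feature_table <- function(synth_args, extended = FALSE, N = 128L) {
  cohort <- generate_cohort(do.call(synth_config, synth_args))
  all_windows <- list()
  for (rec in cohort$recordings) {
    for (ch in imu_channels)
      rec$data[[ch]] <- lowpass_filter(rec$data[[ch]], rec$sampling_rate)
    rec <- add_magnitude_channels(rec)
    events <- detect_foot_strikes(rec$data$az, rec$sampling_rate)
    wins <- segment_and_normalize(rec, events, N = N)
    all_windows <- c(all_windows, unclass(wins))
  }
  windows <- structure(all_windows, class = "stride_windows", N = N)
  build_feature_table(windows, extended = extended)
}

# Hand-built stride windows for feature-level tests.
make_windows <- function(mats, conditions = rep("NF", length(mats)),
                         participant = "P01", duration = 1,
                         indices = seq_along(mats)) {
  chans <- c("acc_x", "acc_y", "acc_z", "acc_mag",
             "gyro_x", "gyro_y", "gyro_z", "gyro_mag")
  windows <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    colnames(m) <- chans
    list(participant_id = participant, condition = conditions[i],
         stride_index = indices[i], duration = duration, data = m)
  })
  structure(windows, class = "stride_windows", N = nrow(mats[[1]]))
}

# Feature-level tables for classifier tests: per-participant baseline offset
# plus a class shift on the first feature; avoids the signal pipeline.
make_classifier_table <- function(n_participants = 6, n_per_condition = 40,
                                  shift = 3, intercept_sd = 0,
                                  n_features = 5, seed = 1L) {
  set.seed(seed)
  u <- rnorm(n_participants, 0, intercept_sd)
  rows <- lapply(seq_len(n_participants), function(j) {
    cond <- rep(c(0L, 1L), each = n_per_condition)
    X <- matrix(rnorm(length(cond) * n_features), ncol = n_features)
    X[, 1] <- X[, 1] + shift * cond + u[j]
    df <- data.frame(participant = sprintf("P%02d", j), condition = cond,
                     stride_index = seq_along(cond))
    for (k in seq_len(n_features)) df[[paste0("feat", k)]] <- X[, k]
    df
  })
  do.call(rbind, rows)
}

feature_cols <- function(ft) grep("^feat", names(ft), value = TRUE)
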