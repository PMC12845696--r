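#' Stride-to-stride trajectory metrics
#'
#' Summarizes the ordered sequence of one per-stride feature within a
#' participant-by-state recording: mean, population variance, coefficient
#' of variation CV = sigma/mu, and the trajectory sample entropy of the
#' stride-ordered sequence (higher-level irregularity of the gait pattern
#' across strides, as opposed to within-stride SampEn).
#'
#' @param trajectory Numeric per-stride feature sequence in stride order,
#'   length >= 2.
#' @param sampen A \code{\link{sampen_params}} (defaults m = 2, r = 0.2
#'   as for stride-level SampEn).
#' @return Named list: \code{n_strides}, \code{mean}, \code{var},
#'   \code{cv} (\code{NA} when the mean is zero), \code{sampen} (\code{NA}
#'   when the sequence is too short or has no template matches).
#' @export
trajectory_metrics <- function(trajectory, sampen = sampen_params()) {
  n <- length(trajectory)
  if (n < 2) stop("trajectory must have length >= 2")
  mu <- mean(trajectory)
  v <- mean((trajectory - mu)^2)
  cv <- if (mu == 0) NA_real_ else sqrt(v) / mu
  se <- if (n >= sampen$m + 2) {
    as.numeric(sample_entropy(trajectory, sampen))
  } else NA_real_
  list(n_strides = n, mean = mu, var = v, cv = cv, sampen = se)
}

#' Variability table across participants, states and features
#'
#' @param ft A feature table.
#' @param features Per-stride feature columns to summarize (default
#'   \code{acc_mag_rms} and \code{gyro_mag_rms}).
#' @param sampen A \code{\link{sampen_params}}.
#' @return Data frame with columns participant, state ("NF"/"F"), feature,
#'   n_strides, mean, var, cv, sampen; trajectories are ordered by
#'   stride_index within a recording and never cross the NF/F boundary.
#' @export
variability_table <- function(ft, features = c("acc_mag_rms", "gyro_mag_rms"),
                              sampen = sampen_params()) {
  missing <- setdiff(features, names(ft))
  if (length(missing))
    stop("feature(s) not in table: ", paste(missing, collapse = ", "))
  rows <- list()
  for (p in unique(as.character(ft$participant))) {
    for (cond in c(1L, 0L)) {
      sel <- ft$participant == p & ft$condition == cond
      if (sum(sel) < 2) next
      block <- ft[sel, ][order(ft$stride_index[sel]), ]
      for (f in features) {
        tm <- trajectory_metrics(block[[f]], sampen)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, state = if (cond == 1L) "F" else "NF",
          feature = f, n_strides = tm$n_strides, mean = tm$mean,
          var = tm$var, cv = tm$cv, sampen = tm$sampen)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Fatigued-minus-non-fatigued variability deltas
#'
#' Exact F minus NF subtraction of CV and trajectory SampEn for each
#' participant-by-feature pair present in both states; pairs missing a
#' state are skipped with a warning.
#'
#' @param records Variability table from \code{\link{variability_table}}.
#' @return Data frame with columns participant, feature, delta_cv,
#'   delta_sampen.
#' @export
state_deltas <- function(records) {
  req <- c("participant", "state", "feature", "cv", "sampen")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records missing column(s): ", paste(missing, collapse = ", "))
  rows <- list()
  skipped <- 0L
  keys <- unique(records[, c("participant", "feature")])
  for (i in seq_len(nrow(keys))) {
    sel <- records$participant == keys$participant[i] &
      records$feature == keys$feature[i]
    f_row <- records[sel & records$state == "F", ]
    nf_row <- records[sel & records$state == "NF", ]
    if (nrow(f_row) != 1 || nrow(nf_row) != 1) { skipped <- skipped + 1L; next }
    rows[[i]] <- data.frame(participant = keys$participant[i],
                            feature = keys$feature[i],
                            delta_cv = f_row$cv - nf_row$cv,
                            delta_sampen = f_row$sampen - nf_row$sampen)
  }
  if (skipped > 0)
    warning(skipped, " participant-feature pair(s) missing a state; skipped")
  do.call(rbind, c(rows, make.row.names = FALSE))
}
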