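#' Raw IMU recording container
#'
#' One participant-by-condition multichannel recording: time plus tri-axial
#' acceleration (ax, ay, az) and angular velocity (gx, gy, gz), optionally
#' extended with derived magnitude channels amag and gmag.
#'
#' @param participant_id Identifier.
#' @param condition "NF" (non-fatigued) or "F" (fatigued).
#' @param sampling_rate Sampling rate in Hz.
#' @param data Data frame with columns \code{time, ax, ay, az, gx, gy, gz}
#'   (and optionally \code{amag, gmag}); time must be strictly increasing.
#' @return Object of class \code{raw_recording}.
#' @export
raw_recording <- function(participant_id, condition, sampling_rate, data) {
  required <- c("time", raw_channel_names())
  missing <- setdiff(required, names(data))
  if (length(missing))
    stop("recording is missing column(s): ", paste(missing, collapse = ", "))
  if (any(diff(data$time) <= 0)) stop("time must be strictly increasing")
  structure(list(participant_id = participant_id,
                 condition = match.arg(condition, c("NF", "F")),
                 sampling_rate = sampling_rate,
                 data = data),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("IMU recording %s [%s]: %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$condition, nrow(x$data), x$sampling_rate,
              nrow(x$data) / x$sampling_rate))
  invisible(x)
}

metadata_path <- function(path) sub("\\.csv$", ".json", path)

#' Write / read a recording as CSV plus JSON metadata sidecar
#'
#' The channel table is written as delimited text; participant, condition
#' and sampling rate travel in a JSON sidecar next to the CSV
#' (\code{<name>.json}). A write-then-read round trip reproduces channel
#' values to better than 1e-9.
#'
#' @param rec A \code{\link{raw_recording}}.
#' @param path CSV file path.
#' @return \code{write_recording} returns the path invisibly;
#'   \code{read_recording} returns a \code{raw_recording}.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  data.table::fwrite(rec$data, path)
  jsonlite::write_json(list(participant_id = rec$participant_id,
                            condition = rec$condition,
                            sampling_rate = rec$sampling_rate),
                       metadata_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param participant_id,condition,sampling_rate Metadata overrides used
#'   when no JSON sidecar is present.
#' @export
read_recording <- function(path, participant_id = NULL, condition = NULL,
                           sampling_rate = NULL) {
  if (!file.exists(path)) stop("no such recording file: ", path)
  df <- as.data.frame(data.table::fread(path))
  mp <- metadata_path(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    if (is.null(participant_id)) participant_id <- meta$participant_id
    if (is.null(condition)) condition <- meta$condition
    if (is.null(sampling_rate)) sampling_rate <- meta$sampling_rate
  }
  if (is.null(participant_id) || is.null(condition) || is.null(sampling_rate))
    stop("missing metadata sidecar ", mp,
         " and no participant_id/condition/sampling_rate supplied")
  raw_recording(participant_id, condition, sampling_rate, df)
}

#' Low-pass filter specification
#'
#' @param order Butterworth filter order (default 4).
#' @param cutoff Cutoff frequency in Hz (default 20).
#' @param zero_phase Apply forward-backward (zero-phase) filtering so event
#'   timing is not lag-shifted (default TRUE).
#' @return Object of class \code{filter_spec}.
#' @export
filter_spec <- function(order = 4, cutoff = 20, zero_phase = TRUE) {
  stopifnot(order >= 1, cutoff > 0)
  structure(list(order = as.integer(order), cutoff = cutoff,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter and applies it forward and backward
#' (zero phase). Edges are handled by odd-reflection padding so that the
#' output has the input's length and DC is preserved; the effective
#' magnitude response is the squared single-pass response
#' \eqn{|H(f)|^2 = (1 + (f/f_c)^{2\,order})^{-1}}.
#'
#' @param x Numeric series, length > 3 x order.
#' @param sampling_rate Sampling rate in Hz.
#' @param spec A \code{\link{filter_spec}}.
#' @return Filtered series, same length as \code{x}.
#' @export
lowpass_filter <- function(x, sampling_rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= sampling_rate / 2)
    stop("cutoff must be below the Nyquist frequency ", sampling_rate / 2)
  n <- length(x)
  if (n <= 3 * spec$order)
    stop("series too short for filter order ", spec$order)
  bf <- signal::butter(spec$order, spec$cutoff / (sampling_rate / 2),
                       type = "low")
  # pad long enough for the start-up transient to decay inside the pad
  npad <- min(n - 1L,
              as.integer(ceiling(2 * sampling_rate / spec$cutoff)) * spec$order)
  pad_l <- 2 * x[1] - x[seq(npad + 1, 2)]
  pad_r <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xp <- c(pad_l, x, pad_r)
  y <- signal::filter(bf, xp)
  if (spec$zero_phase) {
    y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  }
  as.numeric(y)[npad + seq_len(n)]
}

#' Derive acceleration and angular-velocity magnitude channels
#'
#' Adds \code{amag = sqrt(ax^2 + ay^2 + az^2)} and
#' \code{gmag = sqrt(gx^2 + gy^2 + gz^2)} per sample.
#'
#' @param rec A \code{\link{raw_recording}}.
#' @return The recording with \code{amag} and \code{gmag} columns.
#' @export
add_magnitude_channels <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  d <- rec$data
  rec$data$amag <- sqrt(d$ax^2 + d$ay^2 + d$az^2)
  rec$data$gmag <- sqrt(d$gx^2 + d$gy^2 + d$gz^2)
  rec
}

#' Foot-strike detector parameters
#'
#' @param max_stride_frequency Upper bound of the plausible cadence band in
#'   Hz; the minimum peak separation is \code{0.5 / max_stride_frequency}
#'   seconds (default 2 Hz, i.e. 0.25 s).
#' @param prominence_frac Adaptive prominence threshold as a fraction of the
#'   standard deviation of the filtered vertical channel (default 0.5).
#' @return Object of class \code{detector_params}.
#' @export
detector_params <- function(max_stride_frequency = 2, prominence_frac = 0.5) {
  stopifnot(max_stride_frequency > 0, prominence_frac >= 0)
  structure(list(max_stride_frequency = max_stride_frequency,
                 prominence_frac = prominence_frac),
            class = "detector_params")
}

# Topographic prominence of local maxima: for each candidate, walk outward
# until a strictly higher sample (or a boundary), tracking the minimum on
# each side; prominence = peak - max(left minimum, right minimum).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(i) {
    lmin <- x[i]; k <- i
    while (k > 1 && x[k - 1] <= x[i]) { k <- k - 1; lmin <- min(lmin, x[k]) }
    rmin <- x[i]; k <- i
    n <- length(x)
    while (k < n && x[k + 1] <= x[i]) { k <- k + 1; rmin <- min(rmin, x[k]) }
    x[i] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect foot-strike events in the vertical acceleration
#'
#' Finds local maxima of the (already filtered) vertical series whose
#' topographic prominence exceeds an adaptive threshold, then enforces a
#' minimum separation derived from the plausible cadence band by greedily
#' keeping the highest peaks. Recordings with fewer than two events are
#' flagged as not segmentable.
#'
#' @param x Filtered vertical acceleration series.
#' @param sampling_rate Sampling rate in Hz.
#' @param params A \code{\link{detector_params}}.
#' @return Strictly increasing integer sample indices with attribute
#'   \code{segmentable} (FALSE when fewer than 2 events were found, with a
#'   warning).
#' @export
detect_foot_strikes <- function(x, sampling_rate, params = detector_params()) {
  stopifnot(inherits(params, "detector_params"))
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand)) {
    prom <- peak_prominence(x, cand)
    cand <- cand[prom >= params$prominence_frac * stats::sd(x)]
  }
  min_sep <- max(1L, as.integer(round(
    0.5 / params$max_stride_frequency * sampling_rate)))
  keep <- integer(0)
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  events <- sort(keep)
  segmentable <- length(events) >= 2
  if (!segmentable)
    warning("fewer than 2 foot-strike events detected; signal not segmentable")
  structure(events, segmentable = segmentable)
}

stride_channel_names <- function()
  c("acc_x", "acc_y", "acc_z", "acc_mag",
    "gyro_x", "gyro_y", "gyro_z", "gyro_mag")

# recording column -> stride channel mapping (fixed declared order)
recording_channel_map <- function()
  c(ax = "acc_x", ay = "acc_y", az = "acc_z", amag = "acc_mag",
    gx = "gyro_x", gy = "gyro_y", gz = "gyro_z", gmag = "gyro_mag")

#' Cut and time-normalize stride windows
#'
#' Cuts one half-open window per consecutive foot-strike pair
#' \code{[e_k, e_{k+1})} and resamples each of the 8 channels to exactly
#' \code{N} points by linear interpolation on the normalized time grid, so
#' the window endpoints map to phase 0 and (N-1)/N. Windows shorter than 4
#' source samples are dropped with a warning.
#'
#' @param rec A \code{\link{raw_recording}} with magnitude channels (see
#'   \code{\link{add_magnitude_channels}}).
#' @param events Foot-strike sample indices from
#'   \code{\link{detect_foot_strikes}}.
#' @param N Number of samples per normalized stride (default 128, >= 16).
#' @return Object of class \code{stride_windows}: list of windows, each a
#'   list with \code{participant_id}, \code{condition}, \code{stride_index},
#'   \code{duration} (source duration in seconds) and \code{data}
#'   (\code{N x 8} matrix in fixed channel order).
#' @export
segment_and_normalize <- function(rec, events, N = 128L) {
  stopifnot(inherits(rec, "raw_recording"))
  if (length(events) < 2) stop("need at least 2 foot-strike events")
  if (N < 16) stop("N must be >= 16")
  cmap <- recording_channel_map()
  missing <- setdiff(names(cmap), names(rec$data))
  if (length(missing))
    stop("recording lacks channel(s) ", paste(missing, collapse = ", "),
         "; run add_magnitude_channels() first")
  windows <- list()
  dropped <- 0L
  idx <- 0L
  for (k in seq_len(length(events) - 1L)) {
    e1 <- events[k]; e2 <- events[k + 1L]
    len <- e2 - e1
    if (len < 4L) { dropped <- dropped + 1L; next }
    idx <- idx + 1L
    pos <- e1 + (seq_len(N) - 1) / N * len
    mat <- matrix(NA_real_, N, length(cmap),
                  dimnames = list(NULL, unname(cmap)))
    for (src in names(cmap)) {
      mat[, cmap[[src]]] <- stats::approx(seq_len(nrow(rec$data)),
                                          rec$data[[src]], xout = pos)$y
    }
    windows[[idx]] <- list(participant_id = rec$participant_id,
                           condition = rec$condition,
                           stride_index = idx,
                           duration = len / rec$sampling_rate,
                           data = mat)
  }
  if (dropped > 0)
    warning(dropped, " stride window(s) shorter than 4 samples were dropped")
  structure(windows, class = "stride_windows", N = as.integer(N))
}

#' Flatten stride windows to one long table (and back)
#'
#' The long form has columns participant, condition, stride_index,
#' duration, sample_index (0-based) and the 8 channel columns, suitable for
#' CSV persistence between pipeline stages.
#'
#' @param windows A \code{stride_windows} object.
#' @return \code{windows_to_table}: data frame; \code{table_to_windows}: a
#'   \code{stride_windows} object.
#' @export
windows_to_table <- function(windows) {
  stopifnot(inherits(windows, "stride_windows"))
  do.call(rbind, lapply(windows, function(w) {
    cbind(data.frame(participant = w$participant_id,
                     condition = w$condition,
                     stride_index = w$stride_index,
                     duration = w$duration,
                     sample_index = seq_len(nrow(w$data)) - 1L),
          as.data.frame(w$data))
  }))
}

#' @rdname windows_to_table
#' @param tab Long-form stride table as written by \code{windows_to_table}.
#' @export
table_to_windows <- function(tab) {
  chans <- stride_channel_names()
  required <- c("participant", "condition", "stride_index", "duration",
                "sample_index", chans)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("stride table missing column(s): ", paste(missing, collapse = ", "))
  keys <- unique(tab[, c("participant", "condition", "stride_index")])
  windows <- vector("list", nrow(keys))
  Ns <- integer(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- tab$participant == keys$participant[i] &
      tab$condition == keys$condition[i] &
      tab$stride_index == keys$stride_index[i]
    block <- tab[sel, ][order(tab$sample_index[sel]), ]
    Ns[i] <- nrow(block)
    m <- as.matrix(block[, chans])
    rownames(m) <- NULL
    windows[[i]] <- list(participant_id = keys$participant[i],
                         condition = keys$condition[i],
                         stride_index = keys$stride_index[i],
                         duration = block$duration[1],
                         data = m)
  }
  if (length(unique(Ns)) > 1) stop("inhomogeneous window lengths in table")
  structure(windows, class = "stride_windows", N = Ns[1])
}
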