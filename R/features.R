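#' Sample-entropy parameters
#'
#' @param m Template length (default 2).
#' @param r Matching tolerance as a fraction of the series' (population)
#'   standard deviation (default 0.2).
#' @return Object of class \code{sampen_params}.
#' @export
sampen_params <- function(m = 2L, r = 0.2) {
  stopifnot(m >= 1, r > 0)
  structure(list(m = as.integer(m), r = r), class = "sampen_params")
}

#' Spectral band specification
#'
#' Ordered, non-overlapping half-open frequency bands \code{[f1, f2)} in Hz
#' over which bandpowers are summed. The defaults cover the locomotor
#' (0.5-3 Hz), impact (3-8 Hz) and high-frequency (8-20 Hz) ranges.
#'
#' @param bands List of length-2 numeric vectors.
#' @return Object of class \code{band_spec}.
#' @export
band_spec <- function(bands = list(c(0.5, 3), c(3, 8), c(8, 20))) {
  for (b in bands) stopifnot(length(b) == 2, b[1] < b[2], b[1] > 0)
  edges <- unlist(bands)
  if (length(bands) > 1) {
    for (i in seq_len(length(bands) - 1))
      if (bands[[i + 1]][1] < bands[[i]][2])
        stop("bands must be non-overlapping and increasing")
  }
  structure(list(bands = bands), class = "band_spec")
}

moment_stat_names <- function()
  c("mean", "std", "rms", "min", "max", "skew", "kurt", "energy")

#' Time-domain moment features of one series
#'
#' Population (1/N) moment definitions: mean, standard deviation, RMS,
#' min, max, skewness, non-excess kurtosis (Gaussian -> 3) and energy (sum
#' of squared samples). A zero-variance series returns skew = kurt = 0 and
#' is flagged degenerate rather than erroring, so one flat stride cannot
#' abort a cohort run.
#'
#' @param x Numeric series of length >= 2.
#' @return Named numeric vector (mean, std, rms, min, max, skew, kurt,
#'   energy) with attribute \code{degenerate}.
#' @export
time_domain_features <- function(x) {
  n <- length(x)
  if (n < 2) stop("series must have length >= 2")
  mu <- mean(x)
  sigma2 <- mean((x - mu)^2)
  sigma <- sqrt(sigma2)
  degenerate <- sigma == 0
  if (degenerate) {
    skew <- 0
    kurt <- 0
  } else {
    z <- (x - mu) / sigma
    skew <- mean(z^3)
    kurt <- mean(z^4)
  }
  structure(c(mean = mu, std = sigma, rms = sqrt(mean(x^2)),
              min = min(x), max = max(x), skew = skew, kurt = kurt,
              energy = sum(x^2)),
            degenerate = degenerate)
}

#' Spectral features of one normalized stride series
#'
#' One-sided FFT power spectrum over bins k = 1..floor(N/2) (DC excluded so
#' the mean does not masquerade as periodicity): dominant frequency
#' (argmax-bin frequency), spectral entropy \eqn{-\sum p_k \ln p_k} of the
#' normalized power distribution (natural log, unnormalized), and
#' per-band summed power. The frequency axis uses the stride's effective
#' sampling rate \code{N / duration}, preserving physical Hz after time
#' normalization.
#'
#' @param x Series of length N.
#' @param sampling_rate Effective sampling rate in Hz (N / source duration
#'   for a normalized stride).
#' @param bands A \code{\link{band_spec}}.
#' @return Named numeric vector: \code{fdom}, \code{specent},
#'   \code{bp1..bpM}. An all-zero AC spectrum yields \code{fdom = NA},
#'   \code{specent = 0} and zero bandpowers, with attribute
#'   \code{flat_spectrum = TRUE}.
#' @export
spectral_features <- function(x, sampling_rate, bands = band_spec()) {
  stopifnot(inherits(bands, "band_spec"))
  N <- length(x)
  K <- N %/% 2
  X <- stats::fft(x)
  P <- Mod(X[1 + seq_len(K)])^2
  freqs <- seq_len(K) * sampling_rate / N
  bp <- vapply(bands$bands, function(b) sum(P[freqs >= b[1] & freqs < b[2]]),
               numeric(1))
  names(bp) <- paste0("bp", seq_along(bp))
  total <- sum(P)
  if (total == 0) {
    return(structure(c(fdom = NA_real_, specent = 0, bp), flat_spectrum = TRUE))
  }
  p <- P / total
  pnz <- p[p > 0]
  structure(c(fdom = freqs[which.max(P)], specent = -sum(pnz * log(pnz)), bp),
            flat_spectrum = FALSE)
}

#' Sample entropy of a series
#'
#' SampEn(m, r) = -ln(A/B), where B counts ordered template pairs (i != j)
#' of length m within Chebyshev distance r*sigma and A the analogous count
#' for length m + 1; both counts run over the n - m templates that admit an
#' (m+1)-point extension. Higher values indicate a more irregular series.
#'
#' @param x Numeric series of length >= m + 2.
#' @param params A \code{\link{sampen_params}}; \code{r} is interpreted as
#'   a fraction of the population standard deviation of \code{x}.
#' @return SampEn value; 0 for a constant series; \code{NA} (with attribute
#'   \code{incomputable = TRUE}) when no template matches exist at length m
#'   or m + 1.
#' @export
sample_entropy <- function(x, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"))
  m <- params$m
  n <- length(x)
  if (n < m + 2) stop("series must have length >= m + 2")
  sigma <- sqrt(mean((x - mean(x))^2))
  if (sigma == 0) return(0)  # all templates match at every length
  tol <- params$r * sigma
  nt <- n - m  # templates admitting an (m+1)-extension
  D <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    xk <- x[seq_len(nt) + k]
    D <- pmax(D, abs(outer(xk, xk, "-")))
  }
  B <- sum(D <= tol) - nt
  xm <- x[seq_len(nt) + m]
  D1 <- pmax(D, abs(outer(xm, xm, "-")))
  A <- sum(D1 <= tol) - nt
  if (B == 0 || A == 0)
    return(structure(NA_real_, incomputable = TRUE))
  -log(A / B)
}

#' Build the labeled per-stride feature table
#'
#' One row per stride window. The base matrix holds the 8 moment statistics
#' for each of the 8 channels (64 columns named
#' \code{{acc|gyro}_{x|y|z|mag}_{mean|std|rms|min|max|skew|kurt|energy}}).
#' With \code{extended = TRUE}, per-channel dominant frequency
#' (\code{_fdom}), spectral entropy (\code{_specent}), bandpowers
#' (\code{_bp1..}) and sample entropy (\code{_sampen}) columns are appended;
#' an incomputable SampEn propagates as \code{NA} in the extended columns
#' only. Labels: \code{condition} is 0 for NF and 1 for F.
#'
#' @param windows A \code{stride_windows} object (homogeneous N).
#' @param sampen A \code{\link{sampen_params}}.
#' @param bands A \code{\link{band_spec}}.
#' @param extended Compute spectral/entropy columns (default TRUE).
#' @return Data frame of class \code{feature_table} with key columns
#'   \code{participant}, \code{condition}, \code{stride_index}; attributes
#'   \code{base_features} and \code{extended_features} list the column
#'   registries.
#' @export
build_feature_table <- function(windows, sampen = sampen_params(),
                                bands = band_spec(), extended = TRUE) {
  stopifnot(inherits(windows, "stride_windows"), length(windows) > 0)
  chans <- stride_channel_names()
  base_cols <- as.vector(t(outer(chans, moment_stat_names(), paste, sep = "_")))
  ext_stats <- c("fdom", "specent",
                 paste0("bp", seq_along(bands$bands)), "sampen")
  ext_cols <- as.vector(t(outer(chans, ext_stats, paste, sep = "_")))
  rows <- lapply(windows, function(w) {
    N <- nrow(w$data)
    vals <- numeric(0)
    for (ch in chans) {
      x <- w$data[, ch]
      td <- time_domain_features(x)
      names(td) <- paste(ch, names(td), sep = "_")
      vals <- c(vals, td)
      if (extended) {
        sp <- spectral_features(x, N / w$duration, bands)
        se <- sample_entropy(x, sampen)
        ex <- c(sp, sampen = as.numeric(se))
        names(ex) <- paste(ch, names(ex), sep = "_")
        vals <- c(vals, ex)
      }
    }
    cbind(data.frame(participant = w$participant_id,
                     condition = ifelse(w$condition == "F", 1L, 0L),
                     stride_index = w$stride_index),
          as.data.frame(as.list(vals)))
  })
  ft <- do.call(rbind, rows)
  ordered_cols <- c("participant", "condition", "stride_index", base_cols,
                    if (extended) ext_cols)
  ft <- ft[, ordered_cols]
  structure(ft, class = c("feature_table", "data.frame"),
            base_features = base_cols,
            extended_features = if (extended) ext_cols else character(0))
}

#' Base (moment) feature column names of a feature table
#'
#' Falls back to the canonical 64-name registry when the attribute was lost
#' in a CSV round trip.
#' @param ft A feature table.
#' @return Character vector of base feature column names present in
#'   \code{ft}.
#' @export
base_feature_names <- function(ft) {
  reg <- attr(ft, "base_features")
  if (is.null(reg)) {
    chans <- stride_channel_names()
    reg <- as.vector(t(outer(chans, moment_stat_names(), paste, sep = "_")))
  }
  intersect(reg, names(ft))
}
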