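# Preprocessing: everything the sequence labeler consumes is a 6-channel
# feature matrix at the common 100 Hz analysis rate, per-channel standardised
# with constants fitted on training data only.

ANALYSIS_RATE <- 100
FEATURE_CHANNELS <- c("accel_x", "accel_y", "accel_z",
                      "gyro_x", "gyro_y", "gyro_z")

#' Resample a multi-channel signal
#'
#' Rational resampling with FIR anti-aliasing for downsampling: a 64-tap
#' Hamming-window low-pass (cutoff at 90% of the target Nyquist, unit DC
#' gain) is applied forward-backward (zero phase) with odd-reflection edge
#' padding, then the filtered signal is interpolated at the target sample
#' instants `k / to_rate`.  Output length is `round(T * to_rate / from_rate)`.
#' Equal rates return the input unchanged.
#'
#' @param x numeric vector or a channels-by-samples matrix.
#' @param from_rate,to_rate sampling rates in Hz.
#' @return Resampled vector or matrix (same number of channels).
#' @examples
#' length(resample_signal(sin(2 * pi * 2 * (0:5119) / 512), 512, 100))
#' @export
resample_signal <- function(x, from_rate, to_rate) {
  if (!is.numeric(from_rate) || from_rate <= 0 ||
      !is.numeric(to_rate) || to_rate <= 0)
    stop("sampling rates must be positive")
  if (is.matrix(x)) {
    out <- t(apply(x, 1, resample_signal, from_rate = from_rate,
                   to_rate = to_rate))
    rownames(out) <- rownames(x)
    return(out)
  }
  n <- length(x)
  if (n == 0L) stop("cannot resample an empty signal")
  if (from_rate == to_rate) return(x)
  n_out <- round(n * to_rate / from_rate)
  xf <- x
  if (to_rate < from_rate && n > 1L) {
    ord <- 64L
    h <- as.numeric(signal::fir1(ord, 0.9 * to_rate / from_rate))
    h <- h / sum(h)
    p <- min(3L * ord, n - 1L)
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    xf <- signal::filtfilt(h, 1, xp)[(p + 1):(p + n)]
  }
  t_in <- (seq_len(n) - 1) / from_rate
  t_out <- (seq_len(n_out) - 1) / to_rate
  stats::approx(t_in, xf, xout = t_out, rule = 2)$y
}

#' Fit per-channel normalization constants on training trials
#'
#' Pools the 100 Hz resampled (unstandardised) feature channels of all
#' training trials and computes one mean and SD per channel.  The constants
#' are a function of the training trials only and are reapplied unchanged to
#' held-out data.
#'
#' @param trials list of `trial_recording` objects (the training set).
#' @return List with numeric vectors `mean` and `sd` (length 6, named).
#' @export
fit_normalization <- function(trials) {
  stopifnot(length(trials) >= 1L)
  raw <- lapply(trials, raw_features)
  pooled <- do.call(cbind, raw)
  mu <- rowMeans(pooled)
  sdv <- apply(pooled, 1, stats::sd)
  bad <- which(sdv <= 0 | !is.finite(sdv))
  if (length(bad))
    stop(sprintf("zero-variance channel during normalization fitting: %s",
                 paste(FEATURE_CHANNELS[bad], collapse = ", ")))
  list(mean = setNames(mu, FEATURE_CHANNELS),
       sd = setNames(sdv, FEATURE_CHANNELS))
}

raw_features <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  if (ncol(trial$accel) == 0L) stop("trial has empty IMU channels")
  m <- rbind(trial$accel, trial$gyro)
  m <- resample_signal(m, trial$sample_rate, ANALYSIS_RATE)
  rownames(m) <- FEATURE_CHANNELS
  m
}

#' Assemble the 6-feature input matrix for one trial
#'
#' Resamples the accelerometer and gyroscope channels to 100 Hz, stacks them
#' in the fixed order accel x, y, z then gyro x, y, z, and standardises each
#' channel (subtract mean, divide by SD).  When `norm` is `NULL` the
#' constants are fitted on this trial alone (only appropriate for training
#' data); pass constants from [fit_normalization()] to reuse a training fit
#' on held-out data.
#'
#' @param trial a `trial_recording`.
#' @param norm normalization constants from [fit_normalization()], or `NULL`
#'   to fit on this trial.
#' @return An object of class `feature_matrix`: list with `values` (6 x T),
#'   `sample_rate` (100) and `norm` (the constants used).
#' @export
assemble_features <- function(trial, norm = NULL) {
  m <- raw_features(trial)
  if (is.null(norm)) norm <- fit_normalization(list(trial))
  v <- (m - norm$mean) / norm$sd
  structure(list(values = v, sample_rate = ANALYSIS_RATE, norm = norm),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: 6 x %d @ %g Hz>\n", ncol(x$values),
              x$sample_rate))
  invisible(x)
}

#' Align a label sequence to a feature matrix
#'
#' Resampling can leave the 100 Hz label sequence and feature matrix lengths
#' differing by a sample or two of rounding.  Differences of at most 2
#' samples are reconciled by truncating or padding the labels with their
#' last value; larger differences signal a synchronization bug upstream and
#' are rejected.
#'
#' @param seq a [binary_phase] at the analysis rate.
#' @param features a `feature_matrix` (or an integer length).
#' @return A [binary_phase] of exactly the feature length.
#' @export
align_labels <- function(seq, features) {
  stopifnot(inherits(seq, "binary_phase"))
  target <- if (inherits(features, "feature_matrix")) ncol(features$values)
            else as.integer(features)
  n <- length(seq$values)
  if (abs(n - target) > 2L)
    stop(sprintf("label length %d and feature length %d differ by more than 2 samples",
                 n, target))
  v <- seq$values
  if (n > target) v <- v[seq_len(target)]
  if (n < target) v <- c(v, rep(v[n], target - n))
  binary_phase(v, seq$sample_rate, seq$effector)
}
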