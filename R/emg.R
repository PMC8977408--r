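## ---------------------------------------------------------------------
## Surface EMG preprocessing and time-domain feature extraction.
##
## Six features per muscle on a sliding window: mean absolute value,
## zero crossings, slope sign changes, waveform length, and the first
## two coefficients of a 4th-order Burg autoregressive model. With the
## default 200 ms window advanced by 50 ms (150 ms overlap) the feature
## stream runs at 20 Hz; 8 channels x 6 features = 48 columns.
## ---------------------------------------------------------------------

EMG_FEATURES <- c("mav", "zc", "ssc", "wl", "ar1", "ar2")

#' Construct an EMG recording object
#'
#' @param signals numeric matrix, samples x channels, with channel
#'   (muscle) column names; a data.frame with a `time` column is also
#'   accepted.
#' @param sampleRateHz sampling rate, Hz; must exceed twice the 450 Hz
#'   filter cut-off.
#' @param timeOriginS time of the first sample, seconds.
#' @return an [EMGRecording-class].
#' @export
emgRecording <- function(signals, sampleRateHz = 1200, timeOriginS = 0) {
  if (is.data.frame(signals)) {
    if ("time" %in% names(signals)) {
      timeOriginS <- signals$time[1]
      signals$time <- NULL
    }
    signals <- as.matrix(signals)
  }
  new("EMGRecording", signals = signals, sampleRateHz = sampleRateHz,
      timeOriginS = timeOriginS)
}

#' Band-pass filter and de-offset raw EMG
#'
#' Per channel: subtracts the channel mean, then applies a zero-phase
#' (forward-backward) Butterworth band-pass of design order 4 with
#' cut-offs at 20 and 450 Hz. Output has the same length and rate as the
#' input. An all-constant channel comes back as all zeros.
#'
#' @param rec an [EMGRecording-class].
#' @param lowHz,highHz band edges, Hz.
#' @param order Butterworth design order.
#' @return a filtered [EMGRecording-class].
#' @export
preprocessEmg <- function(rec, lowHz = 20, highHz = 450, order = 4) {
  stopifnot(is(rec, "EMGRecording"))
  fs <- rec@sampleRateHz
  if (fs <= 2 * highHz)
    stopNamed("myofuse_sample_rate_too_low",
              "sample rate %g Hz is too low for a %g Hz cut-off", fs, highHz)
  if (nrow(rec@signals) <= 10 * order)
    stopNamed("myofuse_signal_too_short",
              "signal too short to filter (need > %d samples)", 10 * order)
  bp <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  out <- apply(rec@signals, 2, function(x) {
    x <- x - mean(x)
    if (all(x == 0)) return(x)
    signal::filtfilt(bp, x)
  })
  colnames(out) <- colnames(rec@signals)
  initialize(rec, signals = out)
}

#' Time-domain EMG window features
#'
#' The classic time-domain feature set computed on one analysis window:
#' `mav()` mean absolute value; `zeroCrossings()` count of adjacent
#' sample pairs of opposite sign whose step exceeds the deadband;
#' `slopeSignChanges()` count of interior samples where the product of
#' the backward and forward differences exceeds the deadband;
#' `waveformLength()` sum of absolute first differences;
#' `arCoefficients()` the first two coefficients of an order-4 Burg
#' autoregressive fit under the convention
#' \eqn{x_t \approx \sum_k a_k x_{t-k}}.
#'
#' @param window numeric vector of samples.
#' @param deadband non-negative threshold (signal units for `zc`,
#'   squared units for `ssc`).
#' @param order autoregressive model order.
#' @return `mav`/`waveformLength`: non-negative real; `zeroCrossings`/
#'   `slopeSignChanges`: non-negative integer count; `arCoefficients`:
#'   numeric length 2.
#' @examples
#' mav(c(1, -1, 1, -1))            # 1
#' zeroCrossings(c(1, -1, 1, -1))  # 3
#' waveformLength(c(0, 1, 0))      # 2
#' @export
mav <- function(window) {
  if (length(window) == 0L)
    stopNamed("myofuse_empty_window", "window must be non-empty")
  mean(abs(window))
}

#' @rdname mav
#' @export
zeroCrossings <- function(window, deadband = 0) {
  if (length(window) == 0L)
    stopNamed("myofuse_empty_window", "window must be non-empty")
  if (deadband < 0)
    stopNamed("myofuse_invalid_argument", "deadband must be non-negative")
  if (length(window) < 2L) return(0L)
  a <- window[-length(window)]
  b <- window[-1]
  sum(a * b < 0 & abs(a - b) > deadband)
}

#' @rdname mav
#' @export
slopeSignChanges <- function(window, deadband = 0) {
  if (length(window) < 3L)
    stopNamed("myofuse_window_too_short",
              "slope sign changes need a window of length >= 3")
  if (deadband < 0)
    stopNamed("myofuse_invalid_argument", "deadband must be non-negative")
  x <- window
  i <- 2:(length(x) - 1)
  sum((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > deadband)
}

#' @rdname mav
#' @export
waveformLength <- function(window) {
  if (length(window) < 2L)
    stopNamed("myofuse_window_too_short",
              "waveform length needs a window of length >= 2")
  sum(abs(diff(window)))
}

#' @rdname mav
#' @export
arCoefficients <- function(window, order = 4) {
  if (length(window) <= 10 * order)
    stopNamed("myofuse_window_too_short",
              "AR fit needs a window longer than %d samples", 10 * order)
  if (stats::var(window) == 0) {
    warning("constant window: AR coefficients set to 0")
    return(c(0, 0))
  }
  fit <- stats::ar.burg(window, aic = FALSE, order.max = order,
                        demean = TRUE)
  unname(fit$ar[1:2])
}

## features of one window, in the fixed column order
.windowFeatures <- function(window, deadband, arOrder) {
  if (all(window == 0)) return(numeric(6))
  ar <- suppressWarnings(arCoefficients(window, arOrder))
  c(mav(window), zeroCrossings(window, deadband),
    slopeSignChanges(window, deadband), waveformLength(window), ar)
}

#' Extract the 6-feature-per-muscle EMG stream on sliding windows
#'
#' Windows of `windowS` seconds advance by `stepS` seconds (defaults
#' 200 ms / 50 ms, i.e. 150 ms overlap and a 20 Hz feature rate). For
#' each window and channel the six features are emitted in the fixed
#' order MAV, ZC, SSC, WL, AR1, AR2; columns are muscle-major
#' (`AM_mav`, `AM_zc`, ..., `SOL_ar2`). Timestamps use the window-end
#' convention.
#'
#' @param rec a preprocessed [EMGRecording-class].
#' @param windowS window length, seconds.
#' @param stepS window advance, seconds; the feature rate is `1/stepS`.
#' @param deadband zero-crossing / slope-sign-change deadband.
#' @param arOrder autoregressive model order.
#' @return an [EMGFeatureStream-class] with
#'   `floor((duration - windowS)/stepS) + 1` rows and
#'   `6 * ncol(signals)` columns.
#' @export
extractEmgFeatures <- function(rec, windowS = 0.200, stepS = 0.050,
                               deadband = 0, arOrder = 4) {
  stopifnot(is(rec, "EMGRecording"))
  assertScalarPositive(windowS, "windowS")
  assertScalarPositive(stepS, "stepS")
  if (windowS < stepS)
    stopNamed("myofuse_invalid_argument", "windowS must be >= stepS")
  fs <- rec@sampleRateHz
  n <- nrow(rec@signals)
  wlen <- round(windowS * fs)
  step <- round(stepS * fs)
  duration <- n / fs
  if (duration < windowS)
    stopNamed("myofuse_signal_too_short",
              "recording (%.3f s) is shorter than one window (%.3f s)",
              duration, windowS)
  nWin <- floor((n - wlen) / step) + 1L
  nCh <- ncol(rec@signals)
  feats <- matrix(0, nWin, 6L * nCh)
  for (w in seq_len(nWin)) {
    i0 <- (w - 1L) * step
    idx <- (i0 + 1L):(i0 + wlen)
    for (ch in seq_len(nCh)) {
      feats[w, (6L * (ch - 1L) + 1L):(6L * ch)] <-
        .windowFeatures(rec@signals[idx, ch], deadband, arOrder)
    }
  }
  colnames(feats) <- as.vector(t(outer(colnames(rec@signals), EMG_FEATURES,
                                       paste, sep = "_")))
  ts <- rec@timeOriginS + (seq_len(nWin) - 1L) * (step / fs) + wlen / fs
  new("EMGFeatureStream", timestamps = ts, features = feats,
      rateHz = fs / step)
}
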