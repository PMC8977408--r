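mkRec <- function(x, fs = 1200) {
  emgRecording(matrix(x, ncol = 1, dimnames = list(NULL, "RF")),
               sampleRateHz = fs)
}

test_that("preprocessing removes DC and keeps the 20-450 Hz band", {
  fs <- 1200
  n <- fs * 4
  t <- (seq_len(n) - 1) / fs

  const <- preprocessEmg(mkRec(rep(5, n)))
  expect_lt(max(abs(const@signals)), 1e-9)

  ampAt <- function(freqHz) {
    out <- preprocessEmg(mkRec(sin(2 * pi * freqHz * t)))@signals[, 1]
    mid <- out[(n / 4):(3 * n / 4)]   # avoid filtfilt edge transients
    max(abs(mid))
  }
  a100 <- ampAt(100)
  expect_lt(abs(a100 - 1), 0.05)
  # cross-check against the designed filter's own frequency response,
  # evaluated directly from the transfer-function polynomials
  bp <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  zi <- exp(-1i * 2 * pi * 100 / fs * (seq_along(bp$b) - 1))
  H <- Mod(sum(bp$b * zi) / sum(bp$a * zi))^2  # |H|^2: zero-phase filtering
  expect_equal(a100, H, tolerance = 0.05)
  expect_lt(ampAt(5), 0.25 * a100)

  expect_error(preprocessEmg(mkRec(rnorm(n), fs = 800)),
               class = "myofuse_sample_rate_too_low")
})

test_that("window primitives match their closed-form examples", {
  expect_equal(mav(c(1, -1, 1, -1)), 1)
  expect_equal(mav(rep(0, 10)), 0)
  expect_equal(mav(c(3, -4)), 3.5)
  expect_error(mav(numeric(0)), class = "myofuse_empty_window")

  expect_equal(zeroCrossings(c(1, -1, 1, -1)), 3)
  expect_equal(zeroCrossings(rep(2, 10)), 0)
  # one period of a 64-sample sinusoid, phased so both crossings fall
  # strictly inside the window and no sample is exactly zero
  s <- sin(2 * pi * ((0:63) + 0.5) / 64 - pi / 4)
  brute <- sum(s[-64] * s[-1] < 0)
  expect_equal(brute, 2)
  expect_equal(zeroCrossings(s), brute)
  expect_error(zeroCrossings(1:3, deadband = -1),
               class = "myofuse_invalid_argument")

  expect_equal(slopeSignChanges(1:10), 0)
  expect_equal(slopeSignChanges(rep(1, 5)), 0)
  expect_equal(slopeSignChanges(c(0, 1, 0, 1, 0)), 3)
  expect_error(slopeSignChanges(1:2), class = "myofuse_window_too_short")

  expect_equal(waveformLength(rep(3, 7)), 0)
  expect_equal(waveformLength(c(0, 1, 0)), 2)
  expect_equal(waveformLength(seq(0, 2.5, by = 0.25)), 10 * 0.25)
})

test_that("Burg AR coefficients recover known processes", {
  set.seed(101)
  wn <- rnorm(4800)
  expect_lt(max(abs(arCoefficients(wn))), 0.1)

  ar1 <- as.numeric(arima.sim(list(ar = 0.5), 4800))
  c1 <- arCoefficients(ar1)
  expect_lt(abs(c1[1] - 0.5), 0.05)

  ar2 <- as.numeric(arima.sim(list(ar = c(0.5, -0.25)), 4800))
  c2 <- arCoefficients(ar2)
  expect_lt(abs(c2[1] - 0.5), 0.05)
  expect_lt(abs(c2[2] + 0.25), 0.05)

  expect_warning(z <- arCoefficients(rep(1, 100)), "constant")
  expect_equal(z, c(0, 0))
})

test_that("sliding-window extraction has the stated shape, rate and zeros", {
  fs <- 1200
  set.seed(7)
  sig <- matrix(rnorm(fs * 10 * 8), ncol = 8)
  colnames(sig) <- EMG_MUSCLES
  fstr <- extractEmgFeatures(emgRecording(sig, fs))
  expect_equal(ncol(featureMatrix(fstr)), 48)
  expect_equal(nrow(featureMatrix(fstr)), floor((10 - 0.2) / 0.05) + 1)
  expect_equal(fstr@rateHz, 20)
  expect_equal(unique(round(diff(timestamps(fstr)), 9)), 0.05)

  zeros <- extractEmgFeatures(mkRec(rep(0, fs * 2)))
  expect_true(all(featureMatrix(zeros) == 0))

  expect_error(extractEmgFeatures(mkRec(rnorm(100))),
               class = "myofuse_signal_too_short")
})

test_that("every emitted feature equals the brute-force window loop exactly", {
  fs <- 1000
  set.seed(33)
  sig <- matrix(rnorm(fs * 2 * 2), ncol = 2,
                dimnames = list(NULL, c("RF", "TA")))
  got <- featureMatrix(extractEmgFeatures(emgRecording(sig, fs),
                                          windowS = 0.25, stepS = 0.1))
  want <- bruteWindowFeatures(sig, fs, 0.25, 0.1)
  expect_identical(unname(got), want)
})

test_that("feature scaling equivariance under channel gain", {
  fs <- 1200
  set.seed(55)
  x <- rnorm(fs * 2)
  f1 <- featureMatrix(extractEmgFeatures(mkRec(x)))
  f2 <- featureMatrix(extractEmgFeatures(mkRec(3.7 * x)))
  expect_equal(f2[, "RF_mav"], 3.7 * f1[, "RF_mav"], tolerance = 1e-12)
  expect_equal(f2[, "RF_wl"], 3.7 * f1[, "RF_wl"], tolerance = 1e-12)
  expect_identical(f2[, "RF_zc"], f1[, "RF_zc"])
  expect_identical(f2[, "RF_ssc"], f1[, "RF_ssc"])
  expect_equal(f2[, c("RF_ar1", "RF_ar2")], f1[, c("RF_ar1", "RF_ar2")],
               tolerance = 1e-9)
})

test_that("MAV tracks latent activation across windows", {
  tpl <- makeGaitTemplate("level_walk", seed = 8)
  trial <- generateTrial(tpl, nStrides = 5, seed = 17)
  fstr <- extractEmgFeatures(preprocessEmg(trial@emg))
  ts <- timestamps(fstr)
  act <- approx(trial@latent$time, trial@latent$activations[, "MG"],
                xout = ts - 0.1)$y  # window centre
  expect_gt(cor(featureMatrix(fstr)[, "MG_mav"], act,
                method = "spearman"), 0.8)
})
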