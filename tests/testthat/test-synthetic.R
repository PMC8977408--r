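tasks <- c("level_walk", "incline_walk", "decline_walk",
           "stair_ascent", "stair_descent")

test_that("templates are deterministic, physiologic and task-distinct", {
  expect_identical(makeGaitTemplate("level_walk", seed = 1),
                   makeGaitTemplate("level_walk", seed = 1))
  expect_error(makeGaitTemplate("moonwalk"), class = "myofuse_unknown_task")

  phi <- seq(0, 1, length.out = 1024)
  tpls <- lapply(tasks, makeGaitTemplate, seed = 1)
  for (tpl in tpls) {
    for (j in c("hip", "knee", "ankle")) {
      rng <- diff(range(evalJointProfile(tpl, j, phi)))
      expect_gte(rng, 10)
      expect_lte(rng, 90)
    }
  }
  knees <- sapply(tpls, function(t) evalJointProfile(t, "knee", phi))
  for (i in 1:4) for (j in (i + 1):5)
    expect_gte(max(abs(knees[, i] - knees[, j])), 5)
})

test_that("profiles are periodic in value and slope, activations non-negative", {
  tpl <- makeGaitTemplate("stair_ascent", seed = 3)
  eps <- 1e-6
  for (j in c("hip", "knee", "ankle")) {
    v0 <- evalJointProfile(tpl, j, c(0, eps))
    v1 <- evalJointProfile(tpl, j, c(1 - eps, 1))
    expect_equal(v0[1], v1[2], tolerance = 1e-9)
    expect_equal((v0[2] - v0[1]) / eps, (v1[2] - v1[1]) / eps,
                 tolerance = 1e-3)
  }
  act <- evalActivation(tpl, seq(0, 1, length.out = 513))
  expect_true(all(act >= 0))
})

test_that("trial generation: fenceposts, determinism, stream invariants", {
  tpl <- makeGaitTemplate("level_walk", seed = 1)
  trial <- generateTrial(tpl, nStrides = 3, seed = 7)
  expect_length(heelStrikes(trial), 4L)
  expect_true(all(diff(heelStrikes(trial)) > 0))
  expect_error(generateTrial(tpl, nStrides = 0),
               class = "myofuse_invalid_argument")

  again <- generateTrial(tpl, nStrides = 3, seed = 7)
  expect_identical(trial@kinematics, again@kinematics)
  expect_identical(trial@emg@signals, again@emg@signals)
  expect_identical(trial@ultrasound@frames, again@ultrasound@frames)

  dur <- max(trial@kinematics$time)
  nE <- nrow(trial@emg@signals)
  expect_lt(abs(dur - (nE - 1) / trial@emg@sampleRateHz), 1 / 100 + 1e-9)
  expect_true(all(trial@ultrasound@frames >= 0 &
                    trial@ultrasound@frames <= 255))
})

test_that("zero-noise kinematics reproduce the template at the phase clock", {
  tpl <- makeGaitTemplate("decline_walk", seed = 2)
  trial <- generateTrial(tpl, nStrides = 3, noise = zeroNoiseConfig(),
                         seed = 5)
  hs <- heelStrikes(trial)
  t <- trial@kinematics$time
  k <- pmin(pmax(findInterval(t, hs), 1L), 3L)
  phi <- (t - hs[k]) / diff(hs)[k]
  expect_equal(trial@kinematics$knee_angle,
               evalJointProfile(tpl, "knee", phi), tolerance = 1e-9)
  expect_equal(trial@kinematics$hip_angle,
               evalJointProfile(tpl, "hip", phi), tolerance = 1e-9)
})

test_that("a silent muscle yields a silent EMG channel", {
  tpl <- makeGaitTemplate("level_walk", seed = 4)
  ap <- tpl@activationProfiles
  ap["TA", c("base", "amp")] <- 0
  tpl@activationProfiles <- ap
  trial <- generateTrial(tpl, nStrides = 2, noise = zeroNoiseConfig(),
                         seed = 9)
  hs <- heelStrikes(trial)
  tE <- (seq_len(nrow(trial@emg@signals)) - 1) / trial@emg@sampleRateHz
  stride1 <- tE >= hs[1] & tE < hs[2]
  silent <- mav(trial@emg@signals[stride1, "TA"])
  active <- mav(trial@emg@signals[stride1, "MG"])
  expect_lt(silent, 0.01 * active)
})

test_that("generated EMG is band-limited to the preprocessing band", {
  tpl <- makeGaitTemplate("level_walk", seed = 1)
  trial <- generateTrial(tpl, nStrides = 6, seed = 21)
  x <- trial@emg@signals[, "RF"]
  n <- length(x)
  fs <- trial@emg@sampleRateHz
  pw <- Mod(fft(x - mean(x)))[1:(n %/% 2)]^2
  freq <- (seq_len(n %/% 2) - 1) * fs / n
  expect_lt(sum(pw[freq < 10]) / sum(pw), 0.05)
  expect_lt(sum(pw[freq > 500]) / sum(pw), 0.05)
})

test_that("ultrasound band intensity tracks latent activation monotonically", {
  tpl <- makeGaitTemplate("incline_walk", seed = 6)
  trial <- generateTrial(tpl, nStrides = 4, noise = zeroNoiseConfig(),
                         seed = 13)
  fr <- frames(trial@ultrasound)
  nF <- dim(fr)[3]
  rfRows <- 1:40  # superficial third = RF band under the default geometry
  bandMean <- vapply(seq_len(nF), function(f) mean(fr[rfRows, , f]),
                     numeric(1))
  tUs <- (seq_len(nF) - 1) / trial@ultrasound@frameRateHz
  actRf <- trial@latent$activations[match(round(tUs, 6),
                                          round(trial@latent$time, 6)), "RF"]
  expect_gt(cor(bandMean, actRf, method = "spearman"), 0.99)
})

test_that("modality visibility gives each joint single-modality-blind latents", {
  vis <- latentVisibility("anterior")
  expect_setequal(vis$smg, c("RF", "VM", "VI"))
  expect_false(any(c("VM", "VI", "ST") %in% vis$emg))
  W <- makeGaitTemplate("level_walk", seed = 1)@coupling
  emgOnly <- setdiff(vis$emg, vis$smg)
  smgOnly <- setdiff(vis$smg, vis$emg)
  for (j in rownames(W)) {
    expect_gt(sum(abs(W[j, emgOnly])), 0)
    expect_gt(sum(abs(W[j, smgOnly])), 0)
  }
})

test_that("dataset generation: one trial per task, reproducible, walk-heavy", {
  cfg <- datasetConfig(stridesPerTask = c(level_walk = 4L, incline_walk = 4L,
                                          decline_walk = 4L, stair_ascent = 2L,
                                          stair_descent = 3L))
  d1 <- generateGaitDataset(cfg, seed = 3)
  expect_named(d1, tasks)
  d2 <- generateGaitDataset(cfg, seed = 3)
  expect_identical(d1$level_walk@emg@signals, d2$level_walk@emg@signals)
  expect_identical(d1$stair_ascent@ultrasound@frames,
                   d2$stair_ascent@ultrasound@frames)
  expect_gt(length(heelStrikes(d1$level_walk)),
            length(heelStrikes(d1$stair_ascent)))
  expect_error(datasetConfig(tasks = character(0)),
               class = "myofuse_invalid_argument")
})
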