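mkEmgStream <- function(ts, ncol = 3) {
  new("EMGFeatureStream", timestamps = ts,
      features = matrix(seq_along(ts) + rep(seq_len(ncol), each = length(ts)),
                        length(ts), ncol), rateHz = 1 / diff(ts[1:2]))
}
mkSmgStream <- function(ts, nblocks = 4) {
  new("SMGFeatureStream", timestamps = ts,
      features = matrix(rep(seq_along(ts), 2 * nblocks), length(ts)),
      gridShape = c(as.integer(nblocks), 1L), frameRateHz = 1 / diff(ts[1:2]))
}

test_that("alignment: identity mapping, interpolation, overlap trimming", {
  ts <- seq(0.2, 4, by = 0.05)
  emg <- mkEmgStream(ts)
  smg <- mkSmgStream(ts)  # same clock: nearest-frame mapping is identity
  kin <- data.frame(time = seq(0, 4.5, by = 0.01),
                    hip_angle = 7, knee_angle = 7, ankle_angle = 7,
                    hip_velocity = 0, knee_velocity = 0, ankle_velocity = 0)
  ds <- alignStreams(emg, smg, kin, task = "level_walk")
  expect_equal(timestamps(ds), ts)
  expect_identical(ds@Xsmg, smg@features)
  expect_true(all(ds@Y[, "hip_angle"] == 7))

  # kinematics covering only part of the stream trims the clock
  kinShort <- kin[kin$time <= 2, ]
  ds2 <- alignStreams(emg, smg, kinShort)
  expect_lte(max(timestamps(ds2)), 2 + 1e-9)

  kinOut <- kin; kinOut$time <- kinOut$time + 100
  expect_error(alignStreams(emg, smg, kinOut),
               class = "myofuse_empty_overlap")
})

test_that("nearest-frame mapping at 17 Hz is within half a frame interval", {
  ts <- seq(0.2, 6, by = 0.05)
  emg <- mkEmgStream(ts)
  tS <- seq(0, 6.2, by = 1 / 17)
  smg <- mkSmgStream(tS)
  kin <- data.frame(time = seq(0, 6.5, by = 0.01),
                    hip_angle = sin(seq(0, 6.5, by = 0.01)),
                    knee_angle = 0, ankle_angle = 0, hip_velocity = 0,
                    knee_velocity = 0, ankle_velocity = 0)
  ds <- alignStreams(emg, smg, kin)
  # recover which frame each row took via the feature value (= frame index)
  mapped <- ds@Xsmg[, 1]
  mappedTimes <- tS[mapped]
  expect_true(all(abs(mappedTimes - timestamps(ds)) <= 1 / (2 * 17) + 1e-9))
  # brute-force nearest neighbour agreement
  for (i in seq_along(timestamps(ds))) {
    d <- abs(tS - timestamps(ds)[i])
    expect_equal(d[mapped[i]], min(d), tolerance = 1e-12)
  }
  # linear interpolation of a smooth target is accurate at 100 Hz
  expect_lt(max(abs(ds@Y[, "hip_angle"] - sin(timestamps(ds)))), 1e-4)
})

test_that("stride segmentation splits rows at heel strikes", {
  ts <- seq(0, 1.95, by = 0.05)
  ds <- new("AlignedDataset", timestamps = ts,
            Xemg = matrix(0, length(ts), 2), Xsmg = matrix(0, length(ts), 2),
            Y = matrix(0, length(ts), 6,
                       dimnames = list(NULL, c("hip_angle", "knee_angle",
                                               "ankle_angle", "hip_velocity",
                                               "knee_velocity",
                                               "ankle_velocity"))),
            task = "level_walk")
  ss <- segmentStrides(ds, c(0, 1, 2))
  st <- strideTable(ss)
  expect_equal(nrow(st), 2)
  expect_equal(st$endRow - st$startRow + 1, c(20L, 20L))
  expect_error(segmentStrides(ds, 0.5), class = "myofuse_too_few_events")
  expect_warning(segmentStrides(ds, c(0, 0.1, 2)), "discarded")
})

test_that("segmentation recovers the generator's stride count under jitter", {
  tpl <- makeGaitTemplate("incline_walk", seed = 12)
  trial <- generateTrial(tpl, nStrides = 8, seed = 23)
  ef <- extractEmgFeatures(preprocessEmg(trial@emg))
  sf <- extractSmgFeatures(trial@ultrasound)
  ds <- alignStreams(ef, sf, trial@kinematics, task = trial@task)
  ss <- segmentStrides(ds, heelStrikes(trial))
  expect_equal(nrow(strideTable(ss)), 8)
})

test_that("pooling concatenates strides and selects modality columns", {
  trials <- tinyDataset(seed = 31, strides = 3L)
  prep <- prepareDatasets(trials)
  pooledF <- buildPooled(prep, "fusion")
  pooledE <- buildPooled(prep, "emg")
  pooledS <- buildPooled(prep, "smg")
  expect_equal(nrow(strideTable(pooledF)), 15)
  expect_equal(ncol(featureMatrix(pooledE)), 48)
  expect_equal(ncol(featureMatrix(pooledS)), 520)
  expect_equal(ncol(featureMatrix(pooledF)), 568)
  expect_error(buildPooled(prep, "sonar"), class = "myofuse_unknown_modality")

  # row conservation and exact partition by strides
  st <- strideTable(pooledF)
  rows <- unlist(Map(seq.int, st$startRow, st$endRow))
  expect_equal(length(rows), nrow(featureMatrix(pooledF)))
  expect_identical(sort(rows), seq_len(nrow(featureMatrix(pooledF))))
  # all modalities share the row structure
  expect_equal(nrow(featureMatrix(pooledE)), nrow(featureMatrix(pooledF)))
  expect_identical(strideTable(pooledE), strideTable(pooledF))
})
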