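mkStrides <- function(counts) {
  # synthetic stride table with 5 rows per stride
  rows <- list(); offset <- 0L
  for (task in names(counts)) {
    for (s in seq_len(counts[[task]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, stride = s, startRow = offset + 1L, endRow = offset + 5L)
      offset <- offset + 5L
    }
  }
  do.call(rbind, rows)
}

test_that("leave-one-stride-out folds partition strides exactly once", {
  s <- mkStrides(c(a = 3, b = 3, c = 3, d = 3, e = 3))
  folds <- losoFolds(s)
  expect_length(folds, 3)
  for (f in folds) expect_equal(nrow(f$testStrides), 5)

  s2 <- mkStrides(c(a = 3, b = 3, c = 3, d = 2, e = 2))
  folds2 <- losoFolds(s2)
  expect_length(folds2, 3)
  expect_equal(nrow(folds2[[3]]$testStrides), 3)

  # every stride is a test stride exactly once; train/test disjoint
  tested <- do.call(rbind, lapply(folds2, `[[`, "testStrides"))
  key <- paste(tested$task, tested$stride)
  expect_setequal(key, paste(s2$task, s2$stride))
  expect_equal(anyDuplicated(key), 0L)
  for (f in folds2) {
    expect_length(intersect(f$testRows, f$trainRows), 0)
    expect_setequal(c(f$testRows, f$trainRows), seq_len(65))
  }

  expect_error(losoFolds(mkStrides(c(a = 3, b = 1))),
               class = "myofuse_too_few_strides")
})

test_that("error metrics match their closed forms and brute force", {
  expect_equal(rmse(1:10, 1:10), 0)
  expect_equal(rmse(1:10, 1:10 + 3), 3)
  set.seed(41)
  a <- rnorm(100); b <- rnorm(100)
  brute <- sqrt(sum((a - b)^2) / 100)
  expect_equal(rmse(a, b), brute, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), class = "myofuse_length_mismatch")

  expect_equal(nrmse(2, c(0, 40)), 5)
  expect_equal(nrmse(0, c(0, 40)), 0)
  expect_error(nrmse(1, rep(3, 5)), class = "myofuse_zero_range")

  expect_equal(adjustedR2(a, a, N = 50, p = 10), 1)
  # R^2 = 0.9, N = 101, p = 10 -> 1 - (100/90)(0.1)
  yt <- as.numeric(scale(rnorm(200)))
  resid <- as.numeric(scale(rnorm(200)))
  yp <- yt - resid * sqrt(0.1 * sum(yt^2) / sum(resid^2))
  expect_equal(adjustedR2(yt, yp, N = 101, p = 10), 1 - (100 / 90) * 0.1,
               tolerance = 1e-4)
  # independent two-step oracle on a random case
  r2 <- 1 - sum((a - b)^2) / sum((a - mean(a))^2)
  expect_equal(adjustedR2(a, b, N = 30, p = 4),
               1 - (29 / 25) * (1 - r2), tolerance = 1e-12)
  expect_error(adjustedR2(a, b, N = 10, p = 9),
               class = "myofuse_invalid_argument")
})

test_that("modality ANOVA matches textbook formulas, gates pairwise tests", {
  same <- data.frame(modality = rep(c("emg", "smg", "fusion"), each = 4),
                     value = rep(1:4, 3))
  resSame <- compareModalities(same)
  expect_equal(resSame$F, 0)
  expect_null(resSame$pairwise)

  set.seed(42)
  two <- data.frame(modality = rep(c("a", "b"), each = 9),
                    value = c(rnorm(9, 0), rnorm(9, 3)))
  resTwo <- compareModalities(two)
  expect_true(resTwo$significant)
  expect_true(all(resTwo$pairwise$significant))

  three <- data.frame(modality = rep(c("a", "b", "c"), times = c(5, 7, 6)),
                      value = rnorm(18, mean = rep(c(0, 1, 3),
                                                   times = c(5, 7, 6))))
  resThree <- compareModalities(three)
  oracle <- bruteAnova(three$value, three$modality)
  expect_equal(resThree$F, oracle$F, tolerance = 1e-10)
  expect_equal(resThree$p, oracle$p, tolerance = 1e-10)

  expect_error(compareModalities(
    data.frame(modality = c("a", "a", "b"), value = 1:3)),
    class = "myofuse_invalid_argument")
})

test_that("Tukey-Kramer pairwise flags match the studentized-range oracle", {
  set.seed(43)
  tbl <- data.frame(modality = rep(c("a", "b", "c"), times = c(6, 8, 7)),
                    value = rnorm(21, mean = rep(c(0, 0.3, 4),
                                                 times = c(6, 8, 7))))
  res <- compareModalities(tbl)
  expect_true(res$significant)
  # unequal-n Tukey-Kramer by hand
  k <- 3; n <- nrow(tbl)
  gm <- tapply(tbl$value, tbl$modality, mean)
  cn <- tapply(tbl$value, tbl$modality, length)
  mse <- sum((tbl$value - gm[tbl$modality])^2) / (n - k)
  pair <- combn(names(gm), 2)
  pAdj <- apply(pair, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / cn[pr[1]] + 1 / cn[pr[2]]))
    q <- abs(gm[pr[1]] - gm[pr[2]]) / se
    ptukey(q, k, n - k, lower.tail = FALSE)
  })
  got <- res$pairwise[order(res$pairwise$comparison), ]
  expect_equal(unname(got$pAdj), unname(pAdj), tolerance = 1e-8)
})

test_that("the cross-validated experiment runs both modalities on shared folds", {
  trials <- tinyDataset(seed = 51, strides = 2L)
  rep <- runExperiment(trials, modalities = c("emg", "fusion"),
                       control = experimentControl(
                         targets = c("hip_angle", "knee_angle"),
                         restarts = 1, maxit = 40))
  m <- metricsTable(rep)
  expect_setequal(unique(m$modality), c("emg", "fusion"))
  expect_setequal(unique(m$target), c("hip_angle", "knee_angle"))
  expect_equal(sum(m$task == "overall"), 4)
  expect_true(all(m$rmse >= 0))
  expect_true(all(m$nrmse >= 0 & is.finite(m$nrmse)))
  expect_true(all(is.na(m$adjR2) | m$adjR2 <= 1))
  # each (modality, task) cell is backed by at least one test stride
  expect_true(all(m$nTestRows > 0))
  expect_silent(auditReport(rep))
  # out-of-fold predictions are complete
  for (mod in names(rep@predictions))
    expect_false(anyNA(rep@predictions[[mod]]))
})

test_that("more kinematic noise strictly degrades every modality", {
  rmseAt <- function(sd) {
    trials <- tinyDataset(seed = 61,
                          strides = 2L,
                          noise = noiseConfig(kinNoiseSdDeg = sd))
    rep <- runExperiment(trials, modalities = c("emg", "smg", "fusion"),
                         control = experimentControl(
                           targets = "knee_angle", restarts = 1, maxit = 30))
    m <- metricsTable(rep)
    tapply(m$rmse[m$task == "overall"], m$modality[m$task == "overall"],
           identity)
  }
  ladder <- sapply(c(0.5, 2, 5), rmseAt)
  for (mod in rownames(ladder))
    expect_true(all(diff(ladder[mod, ]) > 0))
})
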