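## ---------------------------------------------------------------------
## Leave-one-stride-out, task-invariant cross-validation.
##
## Fold i's test set holds the i-th stride of every task that has at
## least i strides; across folds every stride of every task is the test
## stride exactly once. All per-fold statistics (feature/target
## standardisation, hyperparameters) are computed from training rows
## only, and an explicit audit re-derives the standardisation from the
## training rows to prove it.
## ---------------------------------------------------------------------

#' Leave-one-stride-out fold structure
#'
#' @param strides a [PooledStrides-class], [StrideSet-class] or the
#'   stride data.frame itself (`task`, `stride`, `startRow`, `endRow`).
#' @return list of folds; each fold is a list with `testStrides`
#'   (data.frame), `testRows` and `trainRows` (integer vectors). The
#'   number of folds equals the maximum per-task stride count and the
#'   union of test sets is all strides, each exactly once.
#' @export
losoFolds <- function(strides) {
  s <- if (is.data.frame(strides)) strides else strideTable(strides)
  counts <- table(s$task)
  if (any(counts < 2L))
    stopNamed("myofuse_too_few_strides",
              "every task needs at least 2 strides (got: %s)",
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  nFolds <- max(counts)
  allRows <- function(d) unlist(Map(seq.int, d$startRow, d$endRow),
                                use.names = FALSE)
  lapply(seq_len(nFolds), function(i) {
    test <- do.call(rbind, lapply(split(s, s$task), function(d) {
      d <- d[order(d$stride), , drop = FALSE]
      if (nrow(d) >= i) d[i, , drop = FALSE] else NULL
    }))
    rownames(test) <- NULL
    testRows <- sort(allRows(test))
    trainRows <- sort(setdiff(allRows(s), testRows))
    list(testStrides = test, testRows = testRows, trainRows = trainRows)
  })
}

#' Experiment configuration
#'
#' @param targets kinematic targets to model (default all six).
#' @param hyperoptSize training-row subset size used for the marginal-
#'   likelihood search within each fold (prediction is always exact on
#'   all training rows).
#' @param restarts,maxit optimizer restarts and iteration cap per fold.
#' @param seed RNG seed for subset sampling and restarts.
#' @param jitter relative diagonal jitter.
#' @return named list.
#' @export
experimentControl <- function(targets = KIN_TARGETS, hyperoptSize = 400,
                              restarts = 1, maxit = 60, seed = 1L,
                              jitter = 1e-8) {
  list(targets = targets, hyperoptSize = hyperoptSize, restarts = restarts,
       maxit = maxit, seed = as.integer(seed), jitter = jitter)
}

#' Assemble aligned, stride-segmented datasets from trials
#'
#' Runs the per-trial feature pipeline (EMG preprocessing and feature
#' extraction, SMG feature extraction, stream alignment, stride
#' segmentation) for each task's trial.
#'
#' @param trials named list of [SyntheticTrial-class] (one per task).
#' @param blockMm SMG block size, mm.
#' @return list of `list(dataset, strides)` pairs, one per task,
#'   suitable for [buildPooled()].
#' @export
prepareDatasets <- function(trials, blockMm = 3.0) {
  lapply(trials, function(trial) {
    ef <- extractEmgFeatures(preprocessEmg(trial@emg))
    sf <- extractSmgFeatures(trial@ultrasound, blockMm = blockMm)
    ds <- alignStreams(ef, sf, trial@kinematics, task = trial@task)
    ss <- segmentStrides(ds, heelStrikes(trial))
    list(dataset = ds, strides = ss)
  })
}

## fit-and-predict for one fold of one modality, all targets.
## Returns predictions for the test rows plus the audit record.
.foldFitPredict <- function(X, Y, fold, ctl) {
  tr <- fold$trainRows; te <- fold$testRows
  xc <- colMeans(X[tr, , drop = FALSE])
  xs <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  xs[xs < 1e-12] <- 1
  Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, xc), 2, xs, "/")
  Zte <- sweep(sweep(X[te, , drop = FALSE], 2, xc), 2, xs, "/")
  n <- nrow(Ztr)
  sub <- if (n > ctl$hyperoptSize)
    withSeed(ctl$seed, sort(sample.int(n, ctl$hyperoptSize)))
  else seq_len(n)
  D2tr <- sqDistMatrix(Ztr)
  D2sub <- D2tr[sub, sub, drop = FALSE]
  D2cross <- sqDistMatrix(Zte, Ztr)
  gctl <- gprControl(restarts = ctl$restarts, maxit = ctl$maxit,
                     seed = ctl$seed, jitter = ctl$jitter)
  preds <- matrix(NA_real_, length(te), length(ctl$targets),
                  dimnames = list(NULL, ctl$targets))
  conv <- logical(length(ctl$targets))
  for (k in seq_along(ctl$targets)) {
    y <- Y[tr, ctl$targets[k]]
    yc <- mean(y); ys <- stats::sd(y)
    z <- (y - yc) / ys
    opt <- .gprOptimize(D2sub, z[sub], gctl)
    av <- .gprWeights(D2tr, z, opt$params, ctl$jitter)
    Ks <- .rqKernelFromD2(D2cross, opt$params@sigma, opt$params@alpha,
                          opt$params@lengthScale)
    preds[, k] <- yc + ys * as.vector(Ks %*% av)
    conv[k] <- opt$converged
  }
  ## leakage audit: the standardisation must be reproducible from the
  ## training rows alone and must ignore the test rows entirely
  xcCheck <- colMeans(X[tr, , drop = FALSE])
  audit <- list(
    disjoint = length(intersect(tr, te)) == 0L,
    scalerFromTrain = isTRUE(all.equal(xc, xcCheck, tolerance = 1e-12)),
    hyperoptRowsInTrain = all(tr[sub] %in% tr),
    nTrain = n, nTest = length(te), converged = all(conv)
  )
  list(preds = preds, audit = audit)
}

#' Run the full task-invariant cross-validated experiment
#'
#' For each requested modality: pools the stride-segmented datasets,
#' builds the leave-one-stride-out folds (identical across modalities),
#' fits one Gaussian process per kinematic target per fold on training
#' rows only, predicts the held-out strides, and aggregates RMSE,
#' range-normalised RMSE and adjusted R-squared per ambulation task plus
#' the overall (across-task mean) rows.
#'
#' @param trials named list of [SyntheticTrial-class], or the output of
#'   [prepareDatasets()].
#' @param modalities subset of `c("emg", "smg", "fusion")`.
#' @param control an [experimentControl()] list.
#' @return an [EvaluationReport-class].
#' @export
runExperiment <- function(trials, modalities = c("emg", "smg", "fusion"),
                          control = experimentControl()) {
  prepared <- if (is(trials[[1]], "SyntheticTrial"))
    prepareDatasets(trials) else trials
  pooled <- lapply(modalities, function(m) buildPooled(prepared, m))
  names(pooled) <- modalities
  folds <- losoFolds(pooled[[1]])

  metrics <- list()
  predictions <- list()
  audits <- list()
  for (m in modalities) {
    X <- pooled[[m]]@X
    Y <- pooled[[m]]@Y
    predM <- matrix(NA_real_, nrow(X), length(control$targets),
                    dimnames = list(NULL, control$targets))
    nTrainPerFold <- integer(length(folds))
    for (fi in seq_along(folds)) {
      res <- .foldFitPredict(X, Y, folds[[fi]], control)
      predM[folds[[fi]]$testRows, ] <- res$preds
      nTrainPerFold[fi] <- res$audit$nTrain
      audits[[length(audits) + 1L]] <- data.frame(
        modality = m, fold = fi,
        nTrain = res$audit$nTrain, nTest = res$audit$nTest,
        passed = res$audit$disjoint && res$audit$scalerFromTrain &&
          res$audit$hyperoptRowsInTrain,
        converged = res$audit$converged)
    }
    predictions[[m]] <- predM

    st <- pooled[[m]]@strides
    taskOf <- character(nrow(X))
    for (i in seq_len(nrow(st)))
      taskOf[st$startRow[i]:st$endRow[i]] <- st$task[i]
    N <- round(mean(nTrainPerFold))
    p <- ncol(X)
    ## Eq.-4 adjustment is undefined when the training set is not larger
    ## than the variable count; such cells are reported as NA
    adjR2orNA <- function(yt, yp) {
      if (N - 1 - p <= 0) return(NA_real_)
      adjustedR2(yt, yp, N, p)
    }
    for (tg in control$targets) {
      taskRows <- split(seq_len(nrow(X)), taskOf)
      cells <- lapply(names(taskRows), function(task) {
        idx <- taskRows[[task]]
        r <- rmse(Y[idx, tg], predM[idx, tg])
        data.frame(modality = m, target = tg, task = task, rmse = r,
                   nrmse = nrmse(r, Y[idx, tg]),
                   adjR2 = adjR2orNA(Y[idx, tg], predM[idx, tg]),
                   nTestRows = length(idx), N = N, p = p)
      })
      perTask <- do.call(rbind, cells)
      overall <- data.frame(
        modality = m, target = tg, task = "overall",
        rmse = mean(perTask$rmse), nrmse = mean(perTask$nrmse),
        adjR2 = adjR2orNA(Y[, tg], predM[, tg]),
        nTestRows = nrow(X), N = N, p = p)
      metrics[[length(metrics) + 1L]] <- rbind(perTask, overall)
    }
  }

  new("EvaluationReport",
      metrics = do.call(rbind, metrics),
      predictions = predictions,
      folds = folds,
      audit = do.call(rbind, audits),
      config = list(modalities = modalities, control = control))
}

#' Verify the cross-validation leakage audit of a report
#'
#' Checks that (1) across the report's folds every stride was a test
#' stride exactly once, (2) training and test rows were disjoint in
#' every fold, and (3) the per-fold standardisation and hyperparameter
#' subset came from training rows only (as recorded at fitting time).
#'
#' @param report an [EvaluationReport-class].
#' @return TRUE invisibly, or an error describing the violated check.
#' @export
auditReport <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  if (!all(report@audit$passed))
    stopNamed("myofuse_leakage", "a fold failed the leakage audit")
  testRows <- sort(unlist(lapply(report@folds, `[[`, "testRows")))
  nAll <- length(unique(c(unlist(lapply(report@folds, `[[`, "trainRows")),
                          testRows)))
  if (anyDuplicated(testRows) || length(testRows) != nAll)
    stopNamed("myofuse_leakage",
              "test rows do not partition the pooled rows exactly once")
  for (f in report@folds)
    if (length(intersect(f$testRows, f$trainRows)) > 0L)
      stopNamed("myofuse_leakage", "train/test overlap inside a fold")
  invisible(TRUE)
}

#' Replicate the experiment across seeds
#'
#' Generates one synthetic dataset per seed, runs [runExperiment()] on
#' it, and collects the overall (across-task) metric rows -- the
#' per-replicate observations used for modality comparisons (each
#' replicate standing in for one subject).
#'
#' @param seeds integer vector of replicate seeds.
#' @param cfg a [datasetConfig()] list.
#' @param modalities modalities to evaluate.
#' @param control an [experimentControl()] list.
#' @return data.frame: `replicate`, `seed`, `modality`, `target`,
#'   `rmse`, `nrmse`, `adjR2` (overall rows only).
#' @export
runReplicates <- function(seeds, cfg = datasetConfig(),
                          modalities = c("emg", "fusion"),
                          control = experimentControl()) {
  out <- lapply(seq_along(seeds), function(i) {
    trials <- generateGaitDataset(cfg, seed = seeds[i])
    rep <- runExperiment(trials, modalities = modalities, control = control)
    m <- rep@metrics
    ov <- m[m$task == "overall",
            c("modality", "target", "rmse", "nrmse", "adjR2")]
    cbind(replicate = i, seed = seeds[i], ov)
  })
  do.call(rbind, out)
}
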