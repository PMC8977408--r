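## ---------------------------------------------------------------------
## Stream alignment, stride segmentation and pooled dataset assembly.
##
## Common clock = the EMG feature clock (the lowest-rate feature stream,
## 20 Hz by default) restricted to the temporal overlap of all three
## streams. SMG features are mapped by nearest frame time (ties broken
## toward the earlier frame); kinematic targets are linearly
## interpolated. Standardisation is NOT performed here: it is computed
## per cross-validation fold from training rows only.
## ---------------------------------------------------------------------

#' Align EMG features, SMG features and kinematics on a common clock
#'
#' @param emgFeats an [EMGFeatureStream-class].
#' @param smgFeats an [SMGFeatureStream-class].
#' @param kinematics data.frame with a `time` column and the six
#'   kinematic target columns (100 Hz in the study protocol).
#' @param task task label attached to every row.
#' @return an [AlignedDataset-class] on the EMG feature clock.
#' @export
alignStreams <- function(emgFeats, smgFeats, kinematics,
                         task = "unknown") {
  stopifnot(is(emgFeats, "EMGFeatureStream"), is(smgFeats, "SMGFeatureStream"))
  if (!("time" %in% names(kinematics)))
    stopNamed("myofuse_invalid_argument", "kinematics needs a 'time' column")
  tE <- emgFeats@timestamps
  tS <- smgFeats@timestamps
  tK <- kinematics$time
  lo <- max(tE[1], tS[1], tK[1])
  hi <- min(tE[length(tE)], tS[length(tS)], tK[length(tK)])
  keep <- which(tE >= lo - 1e-9 & tE <= hi + 1e-9)
  if (length(keep) == 0L)
    stopNamed("myofuse_empty_overlap",
              "streams have no overlapping time support")
  clock <- tE[keep]

  ## nearest SMG frame per clock tick; ties -> earlier frame
  up <- findInterval(clock, tS)            # frame at or before the tick
  lo_i <- pmax(up, 1L)
  hi_i <- pmin(up + 1L, length(tS))
  dLo <- abs(clock - tS[lo_i])
  dHi <- abs(tS[hi_i] - clock)
  nearest <- ifelse(up < 1L, hi_i, ifelse(dLo <= dHi, lo_i, hi_i))

  targets <- setdiff(names(kinematics), "time")
  ## rule = 2: clock ticks sit inside the overlap up to rounding, so
  ## constant extension only ever acts at the trimmed boundary tick
  Y <- vapply(targets, function(cn) {
    stats::approx(tK, kinematics[[cn]], xout = clock, rule = 2)$y
  }, numeric(length(clock)))
  Y <- matrix(Y, nrow = length(clock), dimnames = list(NULL, targets))

  new("AlignedDataset", timestamps = clock,
      Xemg = emgFeats@features[keep, , drop = FALSE],
      Xsmg = smgFeats@features[nearest, , drop = FALSE],
      Y = Y, task = task)
}

#' Segment an aligned dataset into strides by heel strikes
#'
#' Stride *i* comprises the rows with time in
#' `[heelStrikes[i], heelStrikes[i+1])`. Strides capturing fewer than
#' `minRows` clock ticks are discarded with a warning.
#'
#' @param ds an [AlignedDataset-class].
#' @param heelStrikes ordered heel-strike times, seconds (at least two
#'   inside the dataset's time support).
#' @param minRows minimum rows for a stride to be kept.
#' @return a [StrideSet-class].
#' @export
segmentStrides <- function(ds, heelStrikes, minRows = 4L) {
  stopifnot(is(ds, "AlignedDataset"))
  hs <- sort(heelStrikes)
  if (length(hs) < 2L)
    stopNamed("myofuse_too_few_events",
              "need at least two heel strikes to form a stride")
  ts <- ds@timestamps
  rows <- lapply(seq_len(length(hs) - 1L), function(i) {
    which(ts >= hs[i] - 1e-9 & ts < hs[i + 1] - 1e-9)
  })
  keep <- vapply(rows, length, integer(1)) >= minRows
  if (any(!keep))
    warning(sprintf("discarded %d stride(s) with fewer than %d rows",
                    sum(!keep), minRows))
  rows <- rows[keep]
  if (length(rows) == 0L)
    stopNamed("myofuse_too_few_events", "no usable strides after filtering")
  strides <- data.frame(
    task = ds@task,
    stride = seq_along(rows),
    startRow = vapply(rows, min, integer(1)),
    endRow = vapply(rows, max, integer(1))
  )
  new("StrideSet", strides = strides, nRows = length(ts))
}

#' Pool task trials into one stride-labelled modality dataset
#'
#' Concatenates the aligned rows of all tasks (restricted to rows that
#' belong to a stride) and selects the feature matrix of the requested
#' modality: `"emg"` (48 columns), `"smg"` (2 x blocks columns) or
#' `"fusion"` (SMG then EMG columns, 568 under the defaults).
#'
#' @param datasets list of `list(dataset = AlignedDataset,
#'   strides = StrideSet)` pairs, one per task.
#' @param modality `"emg"`, `"smg"` or `"fusion"`.
#' @return a [PooledStrides-class].
#' @export
buildPooled <- function(datasets, modality = c("fusion", "emg", "smg")) {
  if (!is.character(modality) ||
      !(modality[1] %in% c("emg", "smg", "fusion")))
    stopNamed("myofuse_unknown_modality",
              "modality must be one of emg, smg, fusion")
  modality <- modality[1]
  Xs <- list(); Ys <- list(); st <- list()
  offset <- 0L
  for (d in datasets) {
    ds <- d$dataset; ss <- d$strides
    X <- switch(modality,
      emg = ds@Xemg,
      smg = ds@Xsmg,
      fusion = cbind(ds@Xsmg, ds@Xemg))
    s <- ss@strides
    rowIdx <- unlist(Map(seq.int, s$startRow, s$endRow))
    Xs[[length(Xs) + 1L]] <- X[rowIdx, , drop = FALSE]
    Ys[[length(Ys) + 1L]] <- ds@Y[rowIdx, , drop = FALSE]
    nPer <- s$endRow - s$startRow + 1L
    ends <- cumsum(nPer)
    st[[length(st) + 1L]] <- data.frame(
      task = s$task, stride = s$stride,
      startRow = offset + c(1L, head(ends, -1) + 1L),
      endRow = offset + ends)
    offset <- offset + sum(nPer)
  }
  new("PooledStrides", modality = modality,
      X = do.call(rbind, Xs), Y = do.call(rbind, Ys),
      strides = do.call(rbind, st))
}
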