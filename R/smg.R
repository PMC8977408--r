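## ---------------------------------------------------------------------
## Sonomyography features: per-block mean intensity of each ultrasound
## frame on a 3 x 3 mm grid, flattened superficial-to-deep row-major,
## plus temporal intensity (the per-feature time derivative between
## consecutive frames). Default geometry (120 x 78 px at 0.5 mm/px)
## gives a 20 x 13 block grid and 520 features per frame.
## ---------------------------------------------------------------------

#' Construct an ultrasound sequence object
#'
#' @param frames 3-D numeric array (axial x lateral x frames) or a list
#'   of equal-shape matrices, intensities in `[0, 255]`.
#' @param frameRateHz frame rate, Hz.
#' @param pixelSpacingMm length-2 (axial, lateral) mm per pixel, or a
#'   scalar for isotropic pixels.
#' @param timeOriginS time of the first frame, seconds.
#' @return an [UltrasoundSequence-class].
#' @export
ultrasoundSequence <- function(frames, frameRateHz = 20,
                               pixelSpacingMm = c(0.5, 0.5),
                               timeOriginS = 0) {
  if (is.list(frames))
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1]]), length(frames)))
  if (length(pixelSpacingMm) == 1L)
    pixelSpacingMm <- rep(pixelSpacingMm, 2)
  new("UltrasoundSequence", frames = frames, frameRateHz = frameRateHz,
      pixelSpacingMm = pixelSpacingMm, timeOriginS = timeOriginS)
}

#' Mean intensity of non-overlapping physical blocks of a frame
#'
#' The grid is anchored at the superficial-left corner; each block spans
#' `blockMm` millimetres in both directions (converted to whole pixels
#' via the pixel spacing), and trailing partial blocks at the deep/right
#' edges are discarded.
#'
#' @param frame 2-D intensity matrix (axial rows, superficial first).
#' @param pixelSpacingMm length-2 (axial, lateral) mm per pixel.
#' @param blockMm block edge length, mm.
#' @return matrix of block means, `floor(nrow/blockPx)` x
#'   `floor(ncol/blockPx)`.
#' @examples
#' f <- matrix(77, 12, 12)
#' unique(as.vector(blockMeanIntensity(f, c(0.5, 0.5))))  # 77
#' @export
blockMeanIntensity <- function(frame, pixelSpacingMm, blockMm = 3.0) {
  if (length(pixelSpacingMm) == 1L) pixelSpacingMm <- rep(pixelSpacingMm, 2)
  bAx <- max(1L, round(blockMm / pixelSpacingMm[1]))
  bLat <- max(1L, round(blockMm / pixelSpacingMm[2]))
  gAx <- nrow(frame) %/% bAx
  gLat <- ncol(frame) %/% bLat
  if (gAx < 1L || gLat < 1L)
    stopNamed("myofuse_frame_too_small",
              "frame (%d x %d px) is smaller than one %g mm block",
              nrow(frame), ncol(frame), blockMm)
  out <- matrix(0, gAx, gLat)
  for (i in seq_len(gAx)) {
    rows <- ((i - 1L) * bAx + 1L):(i * bAx)
    for (j in seq_len(gLat)) {
      cols <- ((j - 1L) * bLat + 1L):(j * bLat)
      out[i, j] <- mean(frame[rows, cols])
    }
  }
  out
}

#' Flatten a block grid superficial-to-deep
#'
#' Row-major concatenation: the first (most superficial) row of blocks
#' comes first. The inverse mapping is recoverable from the grid shape
#' with `matrix(v, nrow = gridShape[1], byrow = TRUE)`.
#'
#' @param grid 2-D block-feature matrix (row 1 = most superficial).
#' @return numeric vector of length `prod(dim(grid))`.
#' @export
flattenBlocks <- function(grid) {
  if (length(grid) == 0L)
    stopNamed("myofuse_invalid_argument", "grid must be non-empty")
  as.vector(t(grid))
}

#' Temporal intensity: per-feature time derivative between frames
#'
#' @param featuresT,featuresPrev equal-length feature vectors of the
#'   current and previous frame.
#' @param frameIntervalS time between the frames, seconds.
#' @return `(featuresT - featuresPrev) / frameIntervalS`
#'   (units: intensity per second).
#' @export
temporalIntensity <- function(featuresT, featuresPrev, frameIntervalS) {
  if (length(featuresT) != length(featuresPrev))
    stopNamed("myofuse_length_mismatch",
              "feature vectors must have equal length")
  assertScalarPositive(frameIntervalS, "frameIntervalS")
  (featuresT - featuresPrev) / frameIntervalS
}

#' Extract the sonomyography feature stream from a frame sequence
#'
#' Per frame: block mean intensities (flattened superficial-to-deep)
#' followed by their temporal derivatives, giving `2 * nBlocks` columns
#' (520 for the default geometry). The first frame's temporal features
#' are zero so that frames and feature rows stay aligned one-to-one.
#'
#' @param seq an [UltrasoundSequence-class] with at least two frames.
#' @param blockMm block edge length, mm.
#' @return an [SMGFeatureStream-class]; columns `mean_r<i>_c<j>` then
#'   `temp_r<i>_c<j>`.
#' @export
extractSmgFeatures <- function(seq, blockMm = 3.0) {
  stopifnot(is(seq, "UltrasoundSequence"))
  nF <- dim(seq@frames)[3]
  if (nF < 2L)
    stopNamed("myofuse_too_few_frames",
              "temporal features need at least two frames")
  g1 <- blockMeanIntensity(seq@frames[, , 1], seq@pixelSpacingMm, blockMm)
  gs <- dim(g1)
  nb <- prod(gs)
  means <- matrix(0, nF, nb)
  means[1, ] <- flattenBlocks(g1)
  for (f in 2:nF)
    means[f, ] <- flattenBlocks(
      blockMeanIntensity(seq@frames[, , f], seq@pixelSpacingMm, blockMm))
  dtF <- 1 / seq@frameRateHz
  temps <- rbind(rep(0, nb),
                 (means[-1, , drop = FALSE] -
                    means[-nF, , drop = FALSE]) / dtF)
  lab <- as.vector(t(outer(seq_len(gs[1]), seq_len(gs[2]),
                           function(i, j) sprintf("r%02d_c%02d", i, j))))
  feats <- cbind(means, temps)
  colnames(feats) <- c(paste0("mean_", lab), paste0("temp_", lab))
  ts <- seq@timeOriginS + (seq_len(nF) - 1L) * dtF
  new("SMGFeatureStream", timestamps = ts, features = feats,
      gridShape = as.integer(gs), frameRateHz = seq@frameRateHz)
}
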