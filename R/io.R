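## Plain-text / TIFF artifact exchange: kinematics and EMG as CSV with a
## time column, ultrasound as 8-bit multi-page TIFF plus a JSON sidecar
## (frame rate, pixel spacing), events and latent truth as JSON.

#' Write a synthetic trial to disk
#'
#' Writes `kinematics.csv`, `emg.csv` (time + channel columns),
#' `ultrasound.tiff` (8-bit grayscale, one page per frame) with
#' `ultrasound.json` (frame rate, pixel spacing, time origin),
#' `heel_strikes.json`, `latent.json` and a `manifest.json`.
#'
#' @param trial a [SyntheticTrial-class].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
writeTrial <- function(trial, dir) {
  stopifnot(is(trial, "SyntheticTrial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial@kinematics, file.path(dir, "kinematics.csv"),
                   row.names = FALSE)
  emgDf <- data.frame(
    time = trial@emg@timeOriginS +
      (seq_len(nrow(trial@emg@signals)) - 1L) / trial@emg@sampleRateHz,
    trial@emg@signals, check.names = FALSE)
  utils::write.csv(emgDf, file.path(dir, "emg.csv"), row.names = FALSE)
  writeUltrasound(trial@ultrasound, file.path(dir, "ultrasound.tiff"),
                  file.path(dir, "ultrasound.json"))
  jsonlite::write_json(trial@heelStrikes, file.path(dir, "heel_strikes.json"),
                       digits = NA)
  jsonlite::write_json(
    list(time = trial@latent$time,
         activations = as.data.frame(trial@latent$activations),
         strideScales = as.data.frame(trial@latent$strideScales),
         view = trial@latent$view),
    file.path(dir, "latent.json"), digits = NA)
  jsonlite::write_json(
    list(task = trial@task, seed = trial@seed,
         nStrides = length(trial@heelStrikes) - 1L,
         emgRateHz = trial@emg@sampleRateHz,
         files = list(kinematics = "kinematics.csv", emg = "emg.csv",
                      ultrasound = "ultrasound.tiff",
                      ultrasoundMeta = "ultrasound.json",
                      heelStrikes = "heel_strikes.json",
                      latent = "latent.json")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Ultrasound sequence TIFF I/O
#'
#' `writeUltrasound()` stores frames as an 8-bit grayscale multi-page
#' TIFF plus a JSON sidecar carrying the frame rate, pixel spacing and
#' time origin; `readUltrasound()` reconstructs the sequence (exactly,
#' since frames are integer gray levels).
#'
#' @param seq an [UltrasoundSequence-class].
#' @param tiffPath path of the multi-page TIFF.
#' @param metaPath path of the JSON sidecar.
#' @return `readUltrasound()`: an [UltrasoundSequence-class].
#' @export
writeUltrasound <- function(seq, tiffPath, metaPath) {
  stopifnot(is(seq, "UltrasoundSequence"))
  pages <- lapply(seq_len(dim(seq@frames)[3]),
                  function(f) seq@frames[, , f] / 255)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 8L)
  jsonlite::write_json(
    list(frameRateHz = seq@frameRateHz,
         pixelSpacingMm = seq@pixelSpacingMm,
         timeOriginS = seq@timeOriginS),
    metaPath, auto_unbox = TRUE, digits = NA)
  invisible(tiffPath)
}

#' @rdname writeUltrasound
#' @export
readUltrasound <- function(tiffPath, metaPath) {
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- round(pages[[f]] * 255)
  new("UltrasoundSequence", frames = frames,
      frameRateHz = meta$frameRateHz,
      pixelSpacingMm = meta$pixelSpacingMm,
      timeOriginS = meta$timeOriginS)
}

#' Read an EMG CSV (time + channel columns)
#'
#' @param path CSV with a leading `time` column in seconds.
#' @param sampleRateHz sampling rate; inferred from the time column when
#'   NULL.
#' @return an [EMGRecording-class].
#' @export
readEmgCsv <- function(path, sampleRateHz = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("time" %in% names(df)))
    stopNamed("myofuse_invalid_argument", "EMG CSV needs a 'time' column")
  if (is.null(sampleRateHz))
    sampleRateHz <- 1 / stats::median(diff(df$time))
  emgRecording(df, sampleRateHz = sampleRateHz)
}

#' Read a kinematics CSV (time + target columns)
#'
#' @param path CSV with `time` plus kinematic target columns.
#' @return data.frame.
#' @export
readKinematicsCsv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read heel-strike event times from JSON
#'
#' @param path JSON array of event times in seconds.
#' @return numeric vector.
#' @export
readHeelStrikes <- function(path) {
  as.numeric(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write an evaluation report as JSON and CSV
#'
#' @param report an [EvaluationReport-class].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report@metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(metrics = report@metrics, audit = report@audit),
    file.path(dir, "report.json"), digits = NA)
  invisible(dir)
}
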