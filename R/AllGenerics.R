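#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `timestamps()`
#' (uniform clock of a stream), `featureMatrix()` (features or pooled
#' design matrix), `targetMatrix()` (kinematic targets), `heelStrikes()`,
#' `frames()`, `strideTable()`, `kernelParams()`, `metricsTable()` and
#' `auditTable()`.
#'
#' @param object an object of the documented classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("timestamps", function(object) standardGeneric("timestamps"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("targetMatrix", function(object) standardGeneric("targetMatrix"))

#' @rdname accessors
#' @export
setGeneric("heelStrikes", function(object) standardGeneric("heelStrikes"))

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("strideTable", function(object) standardGeneric("strideTable"))

#' @rdname accessors
#' @export
setGeneric("kernelParams", function(object) standardGeneric("kernelParams"))

#' @rdname accessors
#' @export
setGeneric("metricsTable", function(object) standardGeneric("metricsTable"))

#' @rdname accessors
#' @export
setGeneric("auditTable", function(object) standardGeneric("auditTable"))

#' @rdname accessors
#' @export
setMethod("timestamps", "FeatureStream", function(object) object@timestamps)

#' @rdname accessors
#' @export
setMethod("timestamps", "AlignedDataset", function(object) object@timestamps)

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureStream", function(object) object@features)

#' @rdname accessors
#' @export
setMethod("featureMatrix", "PooledStrides", function(object) object@X)

#' @rdname accessors
#' @export
setMethod("targetMatrix", "AlignedDataset", function(object) object@Y)

#' @rdname accessors
#' @export
setMethod("targetMatrix", "PooledStrides", function(object) object@Y)

#' @rdname accessors
#' @export
setMethod("heelStrikes", "SyntheticTrial", function(object) object@heelStrikes)

#' @rdname accessors
#' @export
setMethod("frames", "UltrasoundSequence", function(object) object@frames)

#' @rdname accessors
#' @export
setMethod("strideTable", "StrideSet", function(object) object@strides)

#' @rdname accessors
#' @export
setMethod("strideTable", "PooledStrides", function(object) object@strides)

#' @rdname accessors
#' @export
setMethod("kernelParams", "GPRModel", function(object) object@params)

#' @rdname accessors
#' @export
setMethod("metricsTable", "EvaluationReport", function(object) object@metrics)

#' @rdname accessors
#' @export
setMethod("auditTable", "EvaluationReport", function(object) object@audit)

setMethod("show", "GaitTemplate", function(object) {
  cat(sprintf("GaitTemplate: %s (stride period %.2f s)\n",
              object@task, object@stridePeriodS))
  rng <- vapply(JOINTS, function(j) {
    p <- evalJointProfile(object, j, seq(0, 1, length.out = 201))
    diff(range(p))
  }, numeric(1))
  cat(sprintf("  joint ranges (deg): hip %.1f, knee %.1f, ankle %.1f\n",
              rng[1], rng[2], rng[3]))
})

setMethod("show", "SyntheticTrial", function(object) {
  cat(sprintf("SyntheticTrial: %s, %d strides, %.1f s\n",
              object@task, length(object@heelStrikes) - 1L,
              max(object@kinematics$time)))
  cat(sprintf("  EMG: %d ch @ %g Hz | US: %dx%d px, %d frames @ %g Hz\n",
              ncol(object@emg@signals), object@emg@sampleRateHz,
              dim(object@ultrasound@frames)[1],
              dim(object@ultrasound@frames)[2],
              dim(object@ultrasound@frames)[3],
              object@ultrasound@frameRateHz))
})

setMethod("show", "EMGRecording", function(object) {
  cat(sprintf("EMGRecording: %d samples x %d channels @ %g Hz\n",
              nrow(object@signals), ncol(object@signals),
              object@sampleRateHz))
})

setMethod("show", "UltrasoundSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "UltrasoundSequence: %d frames of %d x %d px @ %g Hz (%.2g x %.2g mm/px)\n",
    d[3], d[1], d[2], object@frameRateHz,
    object@pixelSpacingMm[1], object@pixelSpacingMm[2]))
})

setMethod("show", "EMGFeatureStream", function(object) {
  cat(sprintf("EMGFeatureStream: %d rows x %d features @ %g Hz\n",
              nrow(object@features), ncol(object@features), object@rateHz))
})

setMethod("show", "SMGFeatureStream", function(object) {
  cat(sprintf("SMGFeatureStream: %d frames x %d features (grid %d x %d)\n",
              nrow(object@features), ncol(object@features),
              object@gridShape[1], object@gridShape[2]))
})

setMethod("show", "AlignedDataset", function(object) {
  cat(sprintf(
    "AlignedDataset (%s): %d rows | EMG %d + SMG %d features, %d targets\n",
    object@task, length(object@timestamps), ncol(object@Xemg),
    ncol(object@Xsmg), ncol(object@Y)))
})

setMethod("show", "StrideSet", function(object) {
  cat(sprintf("StrideSet: %d strides over %d rows\n",
              nrow(object@strides), object@nRows))
})

setMethod("show", "PooledStrides", function(object) {
  cat(sprintf("PooledStrides (%s): %d rows x %d features, %d strides, %d tasks\n",
              object@modality, nrow(object@X), ncol(object@X),
              nrow(object@strides), length(unique(object@strides$task))))
})

setMethod("show", "KernelParams", function(object) {
  cat(sprintf(
    "KernelParams: sigma=%.4g alpha=%.4g lengthScale=%.4g noiseSd=%.4g\n",
    object@sigma, object@alpha, object@lengthScale, object@noiseSd))
})

setMethod("show", "GPRModel", function(object) {
  cat(sprintf("GPRModel: %d training rows x %d features (%s)\n",
              nrow(object@Xtrain), ncol(object@Xtrain),
              if (object@converged) "converged" else "NOT converged"))
  show(object@params)
})

setMethod("show", "EvaluationReport", function(object) {
  m <- object@metrics
  ov <- m[m$task == "overall", c("modality", "target", "rmse", "nrmse", "adjR2")]
  cat("EvaluationReport - overall rows:\n")
  print(ov, row.names = FALSE, digits = 4)
  cat(sprintf("Audit: %d fold checks, all passed: %s\n",
              nrow(object@audit), all(object@audit$passed)))
})
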