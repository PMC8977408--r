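#' @import methods
NULL

TASKS <- c("level_walk", "incline_walk", "decline_walk",
           "stair_ascent", "stair_descent")

JOINTS <- c("hip", "knee", "ankle")

#' EMG channel names
#'
#' The eight lower-limb muscles recorded by surface EMG: adductor magnus
#' (AM), biceps femoris (BF), rectus femoris (RF), vastus lateralis (VL),
#' tensor fascia latae (TFL), medial gastrocnemius (MG), tibialis anterior
#' (TA) and soleus (SOL).
#' @export
EMG_MUSCLES <- c("AM", "BF", "RF", "VL", "TFL", "MG", "TA", "SOL")

## Latent muscle states: the eight EMG-recorded muscles plus vastus
## medialis (VM) and vastus intermedius (VI) (imaged by the anterior
## ultrasound window) and semitendinosus (ST) (imaged by the posterior
## window); none of VM/VI/ST is recorded by surface EMG.
LATENT_MUSCLES <- c(EMG_MUSCLES, "VM", "VI", "ST")

KIN_TARGETS <- c("hip_angle", "knee_angle", "ankle_angle",
                 "hip_velocity", "knee_velocity", "ankle_velocity")

#' Gait template: per-task periodic joint and activation profiles
#'
#' A `GaitTemplate` holds smooth, stride-periodic profiles for one
#' ambulation task: per-joint angle profiles (truncated Fourier series
#' rescaled to a physiologic range, degrees) and per-muscle non-negative
#' activation profiles (periodic von Mises bumps) over gait phase
#' \eqn{\phi \in [0, 1)}. A coupling matrix maps stride-to-stride latent
#' activation scaling onto joint-angle deviations, which is what makes
#' the two sensing modalities complementary by construction.
#'
#' @slot task one of the five ambulation task labels.
#' @slot stridePeriodS nominal stride period in seconds.
#' @slot jointProfiles named list (hip, knee, ankle); each element holds
#'   Fourier coefficients and the range used to rescale the raw series.
#' @slot activationProfiles numeric matrix, one row per latent muscle,
#'   columns `base`, `amp`, `center`, `kappa` of the periodic bump.
#' @slot coupling 3 x 10 matrix (joints x latent muscles) of weights
#'   translating latent stride scaling into joint-angle deviation.
#' @slot couplingDeg deviation amplitude in degrees per unit activation
#'   excess.
#' @export
setClass("GaitTemplate",
  representation(
    task = "character",
    stridePeriodS = "numeric",
    jointProfiles = "list",
    activationProfiles = "matrix",
    coupling = "matrix",
    couplingDeg = "numeric"
  )
)

setValidity("GaitTemplate", function(object) {
  msg <- character()
  if (!(object@task %in% TASKS))
    msg <- c(msg, sprintf("unknown task '%s'", object@task))
  if (length(object@stridePeriodS) != 1L || object@stridePeriodS <= 0)
    msg <- c(msg, "stridePeriodS must be a positive scalar")
  if (!identical(sort(names(object@jointProfiles)), sort(JOINTS)))
    msg <- c(msg, "jointProfiles must be named hip/knee/ankle")
  ap <- object@activationProfiles
  if (nrow(ap) != length(LATENT_MUSCLES) ||
      !all(c("base", "amp", "center", "kappa") %in% colnames(ap)))
    msg <- c(msg, "activationProfiles must have one row per latent muscle")
  else if (any(ap[, "base"] < 0) || any(ap[, "amp"] < 0))
    msg <- c(msg, "activation profiles must be non-negative")
  if (!all(dim(object@coupling) == c(length(JOINTS), length(LATENT_MUSCLES))))
    msg <- c(msg, "coupling must be joints x latent muscles")
  if (length(msg)) msg else TRUE
})

#' Multi-channel surface EMG recording
#'
#' @slot signals numeric matrix, samples x channels; column names are the
#'   muscle labels.
#' @slot sampleRateHz sampling rate, Hz.
#' @slot timeOriginS time of the first sample, seconds.
#' @export
setClass("EMGRecording",
  representation(
    signals = "matrix",
    sampleRateHz = "numeric",
    timeOriginS = "numeric"
  ),
  prototype(sampleRateHz = 1200, timeOriginS = 0)
)

setValidity("EMGRecording", function(object) {
  msg <- character()
  if (length(object@sampleRateHz) != 1L || object@sampleRateHz <= 0)
    msg <- c(msg, "sampleRateHz must be a positive scalar")
  if (is.null(colnames(object@signals)))
    msg <- c(msg, "signals must have channel (muscle) column names")
  if (anyNA(object@signals))
    msg <- c(msg, "signals must be finite")
  if (length(msg)) msg else TRUE
})

#' Grayscale ultrasound (sonomyography) frame sequence
#'
#' @slot frames numeric array, axial rows x lateral columns x frames,
#'   intensities in `[0, 255]`.
#' @slot frameRateHz frame rate, Hz.
#' @slot pixelSpacingMm length-2 numeric, (axial, lateral) mm per pixel.
#' @slot timeOriginS time of the first frame, seconds.
#' @export
setClass("UltrasoundSequence",
  representation(
    frames = "array",
    frameRateHz = "numeric",
    pixelSpacingMm = "numeric",
    timeOriginS = "numeric"
  ),
  prototype(frameRateHz = 20, pixelSpacingMm = c(0.5, 0.5), timeOriginS = 0)
)

setValidity("UltrasoundSequence", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3-D array (axial x lateral x time)")
  if (length(object@pixelSpacingMm) != 2L || any(object@pixelSpacingMm <= 0))
    msg <- c(msg, "pixelSpacingMm must be two positive values")
  if (length(object@frameRateHz) != 1L || object@frameRateHz <= 0)
    msg <- c(msg, "frameRateHz must be a positive scalar")
  rng <- range(object@frames)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    msg <- c(msg, "frame intensities must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' One synthetic multimodal ambulation trial
#'
#' Holds the three synchronous sensor streams (kinematics at 100 Hz, EMG
#' at 1200 Hz, ultrasound frames), heel-strike event times, and the
#' latent ground truth (per-muscle activation series and per-stride
#' scaling factors) the generator used.
#'
#' @slot task ambulation task label.
#' @slot kinematics data.frame: `time` plus the six kinematic targets
#'   (hip/knee/ankle angle in degrees, angular velocity in deg/s).
#' @slot emg an [EMGRecording-class].
#' @slot ultrasound an [UltrasoundSequence-class].
#' @slot heelStrikes strictly increasing event times, seconds.
#' @slot latent list: `time`, `activations` (matrix, samples x latent
#'   muscles), `strideScales` (strides x latent muscles), `latentNames`.
#' @slot template the [GaitTemplate-class] used.
#' @slot seed integer seed the trial was generated with.
#' @export
setClass("SyntheticTrial",
  representation(
    task = "character",
    kinematics = "data.frame",
    emg = "EMGRecording",
    ultrasound = "UltrasoundSequence",
    heelStrikes = "numeric",
    latent = "list",
    template = "GaitTemplate",
    seed = "integer"
  )
)

setValidity("SyntheticTrial", function(object) {
  msg <- character()
  hs <- object@heelStrikes
  if (length(hs) < 2L || any(diff(hs) <= 0))
    msg <- c(msg, "heelStrikes must be >= 2 strictly increasing times")
  dur <- max(object@kinematics$time)
  if (hs[1] < -1e-9 || hs[length(hs)] > dur + 0.011)
    msg <- c(msg, "heelStrikes must lie inside the trial duration")
  if (!all(KIN_TARGETS %in% names(object@kinematics)))
    msg <- c(msg, "kinematics must contain the six target columns")
  if (length(msg)) msg else TRUE
})

#' Feature streams on a uniform clock
#'
#' `FeatureStream` is the virtual parent of [EMGFeatureStream-class]
#' (48 time-domain EMG features at the sliding-window rate) and
#' [SMGFeatureStream-class] (per-block mean-intensity plus temporal
#' intensity features, one row per ultrasound frame).
#'
#' @slot timestamps feature times in seconds (EMG: window-end convention;
#'   SMG: frame times).
#' @slot features numeric matrix, time points x features, named columns.
#' @export
setClass("FeatureStream",
  representation(
    "VIRTUAL",
    timestamps = "numeric",
    features = "matrix"
  )
)

setValidity("FeatureStream", function(object) {
  msg <- character()
  if (nrow(object@features) != length(object@timestamps))
    msg <- c(msg, "features rows must match timestamps")
  if (length(object@timestamps) > 1 && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (any(!is.finite(object@features)))
    msg <- c(msg, "features must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureStream-class
#' @slot rateHz feature rate (1 / window step), Hz.
#' @export
setClass("EMGFeatureStream",
  contains = "FeatureStream",
  representation(rateHz = "numeric")
)

#' @rdname FeatureStream-class
#' @slot gridShape integer length-2, (axial blocks, lateral blocks).
#' @slot frameRateHz ultrasound frame rate, Hz.
#' @export
setClass("SMGFeatureStream",
  contains = "FeatureStream",
  representation(gridShape = "integer", frameRateHz = "numeric")
)

setValidity("SMGFeatureStream", function(object) {
  nb <- prod(object@gridShape)
  if (ncol(object@features) != 2L * nb)
    "feature columns must equal 2 x prod(gridShape)" else TRUE
})

#' Sensor streams aligned on a common clock
#'
#' All streams of one trial resampled onto the EMG feature clock (the
#' lowest-rate feature signal): SMG features mapped by nearest frame,
#' kinematic targets linearly interpolated.
#'
#' @slot timestamps common clock, seconds.
#' @slot Xemg EMG feature matrix (48 columns for 8 channels).
#' @slot Xsmg SMG feature matrix (2 x blocks columns).
#' @slot Y kinematic target matrix, six named columns.
#' @slot task ambulation task label of the trial.
#' @export
setClass("AlignedDataset",
  representation(
    timestamps = "numeric",
    Xemg = "matrix",
    Xsmg = "matrix",
    Y = "matrix",
    task = "character"
  )
)

setValidity("AlignedDataset", function(object) {
  msg <- character()
  n <- length(object@timestamps)
  if (nrow(object@Xemg) != n || nrow(object@Xsmg) != n || nrow(object@Y) != n)
    msg <- c(msg, "all matrices must share the common clock length")
  if (any(!is.finite(object@Xemg)) || any(!is.finite(object@Xsmg)) ||
      any(!is.finite(object@Y)))
    msg <- c(msg, "aligned data must be finite")
  if (length(msg)) msg else TRUE
})

#' Stride segmentation of an aligned dataset
#'
#' @slot strides data.frame with columns `task`, `stride`, `startRow`,
#'   `endRow`: contiguous, non-overlapping, time-ordered row ranges on
#'   the aligned common clock, one per heel-strike interval.
#' @slot nRows row count of the dataset the ranges index into.
#' @export
setClass("StrideSet",
  representation(strides = "data.frame", nRows = "integer")
)

setValidity("StrideSet", function(object) {
  s <- object@strides
  msg <- character()
  need <- c("task", "stride", "startRow", "endRow")
  if (!all(need %in% names(s)))
    return("strides must have task/stride/startRow/endRow columns")
  if (any(s$endRow < s$startRow))
    msg <- c(msg, "stride row ranges must be non-empty")
  rows <- unlist(Map(seq.int, s$startRow, s$endRow))
  if (anyDuplicated(rows))
    msg <- c(msg, "strides must not overlap")
  if (length(rows) && max(rows) > object@nRows)
    msg <- c(msg, "stride rows exceed dataset size")
  if (length(msg)) msg else TRUE
})

#' Pooled, task-labelled stride dataset for one modality
#'
#' Row-wise concatenation of the aligned datasets of all tasks, with the
#' feature matrix restricted to one sensing modality (`emg`, `smg`, or
#' their column-wise `fusion`), plus the stride index used by
#' leave-one-stride-out cross-validation. Column standardisation is
#' deliberately NOT stored here: it is a fitting-time contract, computed
#' from training rows only inside each cross-validation fold.
#'
#' @slot modality `"emg"`, `"smg"` or `"fusion"`.
#' @slot X pooled feature matrix.
#' @slot Y pooled kinematic target matrix (six columns).
#' @slot strides data.frame `task`, `stride`, `startRow`, `endRow` into
#'   the pooled rows.
#' @export
setClass("PooledStrides",
  representation(
    modality = "character",
    X = "matrix",
    Y = "matrix",
    strides = "data.frame"
  )
)

setValidity("PooledStrides", function(object) {
  msg <- character()
  if (!(object@modality %in% c("emg", "smg", "fusion")))
    msg <- c(msg, "modality must be emg, smg or fusion")
  if (nrow(object@X) != nrow(object@Y))
    msg <- c(msg, "X and Y must share rows")
  s <- object@strides
  rows <- unlist(Map(seq.int, s$startRow, s$endRow))
  if (length(rows) != nrow(object@X) ||
      !identical(sort(rows), seq_len(nrow(object@X))))
    msg <- c(msg, "strides must partition the pooled rows exactly")
  if (length(msg)) msg else TRUE
})

#' Rational quadratic kernel hyperparameters
#'
#' @slot sigma signal standard deviation (amplitude), output units.
#' @slot alpha non-negative scale-mixture parameter (dimensionless).
#' @slot lengthScale length-scale l > 0, standardized feature units.
#' @slot noiseSd observation noise standard deviation, output units.
#' @export
setClass("KernelParams",
  representation(
    sigma = "numeric",
    alpha = "numeric",
    lengthScale = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("KernelParams", function(object) {
  msg <- character()
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@lengthScale <= 0) msg <- c(msg, "lengthScale must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Fitted Gaussian process regression model
#'
#' Stores the fitted rational quadratic kernel hyperparameters, the
#' standardized training inputs, the precomputed weight vector
#' \eqn{(K + \sigma_n^2 I)^{-1}(y - m)} and the standardisation
#' parameters (derived from training rows only). The mean function is the
#' constant training-target mean (zero after target standardisation).
#'
#' @slot params a [KernelParams-class].
#' @slot Xtrain standardized training feature matrix.
#' @slot alphaVec precomputed prediction weights.
#' @slot xCenter,xScale per-column feature standardisation.
#' @slot yCenter,yScale target standardisation.
#' @slot converged logical optimizer convergence flag.
#' @slot logMarginal maximised log marginal likelihood (standardized y).
#' @slot control optimizer control list used.
#' @export
setClass("GPRModel",
  representation(
    params = "KernelParams",
    Xtrain = "matrix",
    alphaVec = "numeric",
    xCenter = "numeric",
    xScale = "numeric",
    yCenter = "numeric",
    yScale = "numeric",
    converged = "logical",
    logMarginal = "numeric",
    control = "list"
  )
)

#' Cross-validated evaluation report
#'
#' Output of [runExperiment()]: per (modality, target, task) metric cells
#' plus overall rows, the fold structure, and the leakage audit.
#'
#' @slot metrics data.frame: `modality`, `target`, `task` (including
#'   `"overall"`), `rmse`, `nrmse`, `adjR2`, `nTestRows`, `N` (mean
#'   training rows per fold), `p` (feature count).
#' @slot predictions named list per modality: matrices of out-of-fold
#'   predictions (rows aligned with the pooled dataset).
#' @slot folds the fold list from [losoFolds()].
#' @slot audit data.frame, one row per (modality, fold): leakage checks.
#' @slot config the configuration used.
#' @export
setClass("EvaluationReport",
  representation(
    metrics = "data.frame",
    predictions = "list",
    folds = "list",
    audit = "data.frame",
    config = "list"
  )
)
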