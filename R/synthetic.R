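## ---------------------------------------------------------------------
## Synthetic multimodal gait generator.
##
## The generator emulates the statistical structure the downstream
## analysis assumes: stride-periodic hip/knee/ankle kinematics with
## stride-to-stride variability, surface EMG as activation-modulated
## band-limited (20-450 Hz) noise, and B-mode ultrasound frames whose
## muscle-region intensities follow latent activation states. Latent
## states VM/VI (and ST for the posterior window) are visible to the
## ultrasound image but not to the EMG montage, and several EMG-recorded
## muscles are outside the imaging window, so neither modality alone
## carries all stride-level information -- fusion is informative by
## construction.
## ---------------------------------------------------------------------

STRIDE_PERIODS <- c(level_walk = 1.30, incline_walk = 1.45,
                    decline_walk = 1.50, stair_ascent = 1.60,
                    stair_descent = 1.40)

## Fourier shape coefficients (cos/sin of harmonics 1..4) per joint; the
## shape is rescaled to the task's physiologic range so only its form
## matters here.
.jointShapeBase <- list(
  hip   = list(cos = c(1.00,  0.10,  0.03,  0.00),
               sin = c(0.35, -0.08,  0.02,  0.00)),
  knee  = list(cos = c(-0.45, -0.80,  0.10,  0.03),
               sin = c(-0.90,  0.35,  0.06,  0.00)),
  ankle = list(cos = c(0.30, -0.55, -0.18,  0.02),
               sin = c(0.50,  0.55, -0.10, -0.03))
)

.jointShapeDelta <- list(
  level_walk = list(
    hip   = list(cos = c(0, 0, 0, 0),          sin = c(0, 0, 0, 0)),
    knee  = list(cos = c(0, 0, 0, 0),          sin = c(0, 0, 0, 0)),
    ankle = list(cos = c(0, 0, 0, 0),          sin = c(0, 0, 0, 0))),
  incline_walk = list(
    hip   = list(cos = c(0.15, 0, 0, 0),       sin = c(0, 0.10, 0, 0)),
    knee  = list(cos = c(0, 0.15, 0, 0),       sin = c(0, 0.25, 0, 0)),
    ankle = list(cos = c(0, 0.20, 0, 0),       sin = c(0.10, 0, 0, 0))),
  decline_walk = list(
    hip   = list(cos = c(0, 0.10, 0, 0),       sin = c(-0.20, 0, 0, 0)),
    knee  = list(cos = c(0, -0.30, 0.10, 0),   sin = c(0.15, 0, 0, 0)),
    ankle = list(cos = c(-0.10, 0, 0, 0),      sin = c(-0.25, 0.10, 0, 0))),
  stair_ascent = list(
    hip   = list(cos = c(0, 0.30, 0, 0),       sin = c(0.30, 0, 0, 0)),
    knee  = list(cos = c(0.50, 0.30, 0.15, 0), sin = c(0.40, -0.20, 0, 0)),
    ankle = list(cos = c(-0.30, 0, 0, 0),      sin = c(0, 0.30, 0, 0))),
  stair_descent = list(
    hip   = list(cos = c(-0.25, 0, 0, 0),      sin = c(0, -0.20, 0, 0)),
    knee  = list(cos = c(-0.30, 0.45, -0.10, 0), sin = c(0.55, 0.30, 0, 0)),
    ankle = list(cos = c(0, 0.40, 0, 0),       sin = c(0.30, 0, 0, 0)))
)

## (midpoint, width) of each joint's angular excursion in degrees
.jointRanges <- list(
  level_walk    = list(hip = c(10, 40),  knee = c(31, 62),   ankle = c(-2.5, 25)),
  incline_walk  = list(hip = c(14, 46),  knee = c(33, 66),   ankle = c(0, 28)),
  decline_walk  = list(hip = c(8, 36),   knee = c(34, 68),   ankle = c(-4, 26)),
  stair_ascent  = list(hip = c(17, 58),  knee = c(44, 88),   ankle = c(2, 32)),
  stair_descent = list(hip = c(9, 42),   knee = c(42.5, 85), ankle = c(-5, 34))
)

## periodic activation bumps: base + amp * exp(kappa*(cos(2*pi*(phi-c))-1))
.activationBase <- local({
  m <- cbind(
    base   = rep(0.05, 11),
    amp    = c(0.80, 0.70, 0.90, 0.85, 0.60, 0.95, 0.70, 0.90, 0.85, 0.80, 0.70),
    center = c(0.05, 0.92, 0.08, 0.12, 0.28, 0.42, 0.68, 0.48, 0.16, 0.58, 0.85),
    kappa  = c(5, 6, 5, 5, 4, 7, 4, 6, 5, 5, 6)
  )
  rownames(m) <- c("AM", "BF", "RF", "VL", "TFL", "MG", "TA", "SOL",
                   "VM", "VI", "ST")
  m
})

.taskQuadAmpMult <- c(level_walk = 1, incline_walk = 1.1, decline_walk = 1.05,
                      stair_ascent = 1.25, stair_descent = 1.2)

## joints x latent muscles: how much each latent's stride-level scaling
## deviates the joint angle (in units of couplingDeg degrees).
.defaultCoupling <- local({
  W <- matrix(0, 3, 11, dimnames = list(JOINTS, rownames(.activationBase)))
  W["hip",   c("AM", "TFL", "RF", "VM", "ST")] <- c(1.0, 0.8, 0.3, 0.5, 0.3)
  W["knee",  c("BF", "RF", "VL", "VM", "VI", "ST")] <- c(0.3, 0.5, 0.4, 1.0, 0.8, 0.4)
  W["ankle", c("MG", "TA", "SOL", "VI")] <- c(0.7, 1.0, 0.5, 0.6)
  W
})

#' Which latent muscle states each sensing modality expresses
#'
#' The surface EMG montage records the eight [EMG_MUSCLES]; the
#' ultrasound window images three anterior thigh muscles (RF, VM, VI) or
#' two posterior ones (BF, ST). Latents visible to only one modality are
#' what makes sensor fusion strictly more informative than either stream
#' alone in the synthetic data.
#'
#' @param view `"anterior"` (default) or `"posterior"` transducer
#'   placement.
#' @return list with elements `emg` and `smg` (character vectors of
#'   latent muscle names).
#' @export
latentVisibility <- function(view = c("anterior", "posterior")) {
  view <- match.arg(view)
  list(emg = EMG_MUSCLES,
       smg = if (view == "anterior") c("RF", "VM", "VI") else c("BF", "ST"))
}

#' Build the periodic gait template for one ambulation task
#'
#' Constructs per-joint angle profiles (truncated Fourier series rescaled
#' to a physiologic, task-specific range) and per-muscle activation
#' profiles over gait phase. A small seeded perturbation of the shape
#' coefficients, activation timing and ranges emulates between-subject
#' variation; the same `(task, seed)` pair always yields an identical
#' template.
#'
#' @param task one of `"level_walk"`, `"incline_walk"`, `"decline_walk"`,
#'   `"stair_ascent"`, `"stair_descent"`.
#' @param seed integer RNG seed.
#' @param couplingDeg amplitude (degrees) of the joint-angle deviation
#'   induced per unit of latent stride-scaling excess.
#' @return a [GaitTemplate-class].
#' @examples
#' tpl <- makeGaitTemplate("level_walk", seed = 1)
#' range(evalJointProfile(tpl, "knee", seq(0, 1, by = 0.01)))
#' @export
makeGaitTemplate <- function(task, seed = 1L, couplingDeg = 3) {
  if (!is.character(task) || length(task) != 1L || !(task %in% TASKS))
    stopNamed("myofuse_unknown_task",
              "unknown task label '%s' (expected one of: %s)",
              as.character(task)[1], paste(TASKS, collapse = ", "))
  withSeed(childSeed(seed, match(task, TASKS)), {
    jp <- lapply(JOINTS, function(j) {
      co <- .jointShapeBase[[j]]$cos + .jointShapeDelta[[task]][[j]]$cos +
        rnorm(4, 0, 0.02)
      si <- .jointShapeBase[[j]]$sin + .jointShapeDelta[[task]][[j]]$sin +
        rnorm(4, 0, 0.02)
      mid <- .jointRanges[[task]][[j]][1] + rnorm(1, 0, 1)
      width <- .jointRanges[[task]][[j]][2] * (1 + rnorm(1, 0, 0.02))
      width <- min(max(width, 10.5), 89)
      ## raw extrema on a dense grid, stored for an exact rescale
      grid <- seq(0, 1, length.out = 4097)[-4097]
      raw <- fourierEval(grid, co, si)
      list(cos = co, sin = si, lo = mid - width / 2, hi = mid + width / 2,
           rawMin = min(raw), rawMax = max(raw))
    })
    names(jp) <- JOINTS

    ap <- .activationBase
    ap[, "center"] <- (ap[, "center"] + rnorm(nrow(ap), 0, 0.01)) %% 1
    ap[, "amp"] <- ap[, "amp"] * (1 + rnorm(nrow(ap), 0, 0.05))
    quads <- c("RF", "VL", "VM", "VI")
    ap[quads, "amp"] <- ap[quads, "amp"] * .taskQuadAmpMult[[task]]
    ap[, "amp"] <- pmax(ap[, "amp"], 0)

    new("GaitTemplate", task = task,
        stridePeriodS = unname(STRIDE_PERIODS[[task]]),
        jointProfiles = jp, activationProfiles = ap,
        coupling = .defaultCoupling, couplingDeg = couplingDeg)
  })
}

fourierEval <- function(phi, co, si) {
  out <- numeric(length(phi))
  for (k in seq_along(co))
    out <- out + co[k] * cos(2 * pi * k * phi) + si[k] * sin(2 * pi * k * phi)
  out
}

#' Evaluate a template's joint-angle profile at gait phases
#'
#' @param template a [GaitTemplate-class].
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @param phi gait phases (any real; the profile is 1-periodic).
#' @return joint angle in degrees at each phase.
#' @export
evalJointProfile <- function(template, joint, phi) {
  p <- template@jointProfiles[[match.arg(joint, JOINTS)]]
  raw <- fourierEval(phi %% 1, p$cos, p$sin)
  p$lo + (raw - p$rawMin) / (p$rawMax - p$rawMin) * (p$hi - p$lo)
}

#' Evaluate a template's latent activation profiles at gait phases
#'
#' @param template a [GaitTemplate-class].
#' @param phi gait phases.
#' @param muscles latent muscle names (default: all).
#' @return matrix, `length(phi)` rows x muscles, activations in
#'   `[0, base + amp]`.
#' @export
evalActivation <- function(template, phi,
                           muscles = rownames(template@activationProfiles)) {
  ap <- template@activationProfiles[muscles, , drop = FALSE]
  phi <- phi %% 1
  out <- vapply(seq_len(nrow(ap)), function(i) {
    ap[i, "base"] + ap[i, "amp"] *
      exp(ap[i, "kappa"] * (cos(2 * pi * (phi - ap[i, "center"])) - 1))
  }, numeric(length(phi)))
  out <- matrix(out, nrow = length(phi),
                dimnames = list(NULL, rownames(ap)))
  out
}

#' Noise and variability configuration for trial generation
#'
#' Defaults are the study conditions the generator emulates: 0.5 deg
#' kinematic measurement noise, 5% SD stride-duration jitter, 15%
#' (log-scale SD) stride-to-stride latent activation scaling, a small
#' EMG instrumentation noise floor and 4 gray-level ultrasound frame
#' noise over a static speckle-like texture.
#'
#' @param kinNoiseSdDeg kinematic angle noise SD, degrees.
#' @param strideJitterSd stride-duration jitter SD (fraction of period).
#' @param strideAmpSd log-scale SD of per-stride latent scaling factors.
#' @param emgNoiseSd additive EMG sensor noise SD (units of the unit-
#'   variance carrier).
#' @param emgGain EMG channel gain (arbitrary voltage units).
#' @param usNoiseSd per-pixel per-frame ultrasound noise SD, gray levels.
#' @param usTextureSd static per-pixel texture SD, gray levels.
#' @param usBaseline mean background intensity, gray levels.
#' @param usGain gray levels per unit activation in a muscle band.
#' @return named list.
#' @export
noiseConfig <- function(kinNoiseSdDeg = 0.5, strideJitterSd = 0.05,
                        strideAmpSd = 0.15, emgNoiseSd = 0.002,
                        emgGain = 1, usNoiseSd = 4, usTextureSd = 12,
                        usBaseline = 90, usGain = 60) {
  if (kinNoiseSdDeg < 0 || strideJitterSd < 0 || strideAmpSd < 0 ||
      emgNoiseSd < 0 || usNoiseSd < 0 || usTextureSd < 0 || usGain < 0)
    stopNamed("myofuse_invalid_argument",
              "noise standard deviations must be non-negative")
  list(kinNoiseSdDeg = kinNoiseSdDeg, strideJitterSd = strideJitterSd,
       strideAmpSd = strideAmpSd, emgNoiseSd = emgNoiseSd,
       emgGain = emgGain, usNoiseSd = usNoiseSd,
       usTextureSd = usTextureSd, usBaseline = usBaseline, usGain = usGain)
}

#' @rdname noiseConfig
#' @details `zeroNoiseConfig()` switches off every stochastic element the
#'   configuration controls (measurement noise, stride jitter and
#'   stride-to-stride scaling); the EMG carrier remains stochastic
#'   because surface EMG is itself modelled as modulated noise.
#' @export
zeroNoiseConfig <- function() {
  noiseConfig(kinNoiseSdDeg = 0, strideJitterSd = 0, strideAmpSd = 0,
              emgNoiseSd = 0, usNoiseSd = 0)
}

#' Ultrasound imaging geometry
#'
#' Default field of view is 60 mm axial (the cohort's mean penetration
#' depth) by 39 mm lateral at 0.5 mm/pixel, i.e. 120 x 78 pixels. On a
#' 3 mm block grid this yields 20 x 13 = 260 blocks, hence 520
#' sonomyography features per frame (260 mean-intensity + 260 temporal).
#' The frame rate defaults to 20 Hz so frames align one-to-one with the
#' EMG feature clock.
#'
#' @param axialMm,lateralMm field of view, mm.
#' @param pixelSpacingMm isotropic pixel spacing, mm.
#' @param frameRateHz frame rate, Hz.
#' @param view `"anterior"` (RF/VM/VI bands) or `"posterior"` (BF/ST).
#' @return named list.
#' @export
usGeometry <- function(axialMm = 60, lateralMm = 39, pixelSpacingMm = 0.5,
                       frameRateHz = 20, view = c("anterior", "posterior")) {
  view <- match.arg(view)
  list(axialMm = axialMm, lateralMm = lateralMm,
       pixelSpacingMm = pixelSpacingMm, frameRateHz = frameRateHz,
       view = view,
       nAxialPx = round(axialMm / pixelSpacingMm),
       nLateralPx = round(lateralMm / pixelSpacingMm))
}

## horizontal muscle bands (axial row ranges) of the imaging window
.usBands <- function(geometry) {
  nax <- geometry$nAxialPx
  if (geometry$view == "anterior") {
    cuts <- round(nax * c(0, 1 / 3, 2 / 3, 1))
    list(RF = seq.int(cuts[1] + 1L, cuts[2]),
         VM = seq.int(cuts[2] + 1L, cuts[3]),
         VI = seq.int(cuts[3] + 1L, cuts[4]))
  } else {
    cuts <- round(nax * c(0, 0.5, 1))
    list(BF = seq.int(cuts[1] + 1L, cuts[2]),
         ST = seq.int(cuts[2] + 1L, cuts[3]))
  }
}

#' Generate one synthetic multimodal ambulation trial
#'
#' Builds a stride-phase clock with jittered stride durations, evaluates
#' the template kinematics on it (plus coupling-driven stride-level
#' deviations and measurement noise), derives angular velocity by
#' numerical differentiation of the noisy angle, synthesises EMG as
#' activation-modulated band-limited (20-450 Hz) noise at 1200 Hz, and
#' renders ultrasound frames whose muscle bands brighten with the latent
#' activation of the imaged muscle.
#'
#' @param template a [GaitTemplate-class].
#' @param nStrides number of strides (>= 1); the trial contains exactly
#'   `nStrides + 1` heel strikes.
#' @param noise a [noiseConfig()] list.
#' @param geometry a [usGeometry()] list.
#' @param seed integer RNG seed; identical inputs are bit-identical.
#' @param kinRateHz,emgRateHz kinematic and EMG sampling rates, Hz.
#' @return a [SyntheticTrial-class].
#' @examples
#' tpl <- makeGaitTemplate("level_walk", seed = 1)
#' trial <- generateTrial(tpl, nStrides = 3, seed = 7)
#' length(heelStrikes(trial))  # nStrides + 1
#' @export
generateTrial <- function(template, nStrides, noise = noiseConfig(),
                          geometry = usGeometry(), seed = 1L,
                          kinRateHz = 100, emgRateHz = 1200) {
  if (!is.numeric(nStrides) || length(nStrides) != 1L || nStrides < 1)
    stopNamed("myofuse_invalid_argument", "nStrides must be >= 1")
  nStrides <- as.integer(nStrides)
  stopifnot(is(template, "GaitTemplate"))

  withSeed(seed, {
    ## phase clock with jittered stride durations
    durs <- template@stridePeriodS *
      pmax(0.5, 1 + rnorm(nStrides, 0, noise$strideJitterSd))
    hs <- c(0, cumsum(durs))
    D <- hs[length(hs)]

    lm <- rownames(template@activationProfiles)
    scales <- matrix(exp(rnorm(nStrides * length(lm), 0, noise$strideAmpSd)),
                     nStrides, length(lm), dimnames = list(NULL, lm))

    phaseOf <- function(t) {
      k <- pmin(pmax(findInterval(t, hs), 1L), nStrides)
      list(k = k, phi = (t - hs[k]) / durs[k])
    }

    ## kinematics @ kinRateHz -------------------------------------------
    tKin <- seq.int(0L, floor(D * kinRateHz)) / kinRateHz
    pk <- phaseOf(tKin)
    actBase <- evalActivation(template, pk$phi)
    actScaled <- actBase * scales[pk$k, , drop = FALSE]
    dev <- (actScaled - actBase) %*% t(template@coupling) *
      template@couplingDeg
    ang <- vapply(JOINTS, function(j) {
      evalJointProfile(template, j, pk$phi)
    }, numeric(length(tKin))) + dev
    ang <- ang + matrix(rnorm(length(ang), 0, noise$kinNoiseSdDeg),
                        nrow(ang), ncol(ang))
    vel <- apply(ang, 2, numGradient, dt = 1 / kinRateHz)
    kin <- data.frame(time = tKin,
                      hip_angle = ang[, "hip"], knee_angle = ang[, "knee"],
                      ankle_angle = ang[, "ankle"],
                      hip_velocity = vel[, "hip"],
                      knee_velocity = vel[, "knee"],
                      ankle_velocity = vel[, "ankle"])

    ## EMG @ emgRateHz --------------------------------------------------
    tEmg <- seq.int(0L, floor(D * emgRateHz)) / emgRateHz
    pe <- phaseOf(tEmg)
    actEmgBase <- evalActivation(template, pe$phi, EMG_MUSCLES)
    actEmg <- actEmgBase * scales[pe$k, EMG_MUSCLES, drop = FALSE]
    bp <- signal::butter(4, c(20, 450) / (emgRateHz / 2), type = "pass")
    sig <- vapply(seq_along(EMG_MUSCLES), function(m) {
      carrier <- signal::filtfilt(bp, rnorm(length(tEmg)))
      carrier <- carrier / stats::sd(carrier)
      noise$emgGain * actEmg[, m] * carrier +
        noise$emgNoiseSd * rnorm(length(tEmg))
    }, numeric(length(tEmg)))
    colnames(sig) <- EMG_MUSCLES
    emg <- new("EMGRecording", signals = sig, sampleRateHz = emgRateHz,
               timeOriginS = 0)

    ## ultrasound frames ------------------------------------------------
    nax <- geometry$nAxialPx; nlat <- geometry$nLateralPx
    tUs <- seq.int(0L, floor(D * geometry$frameRateHz)) / geometry$frameRateHz
    pu <- phaseOf(tUs)
    bands <- .usBands(geometry)
    actUsBase <- evalActivation(template, pu$phi, names(bands))
    actUs <- actUsBase * scales[pu$k, names(bands), drop = FALSE]
    texture <- matrix(noise$usBaseline + rnorm(nax * nlat, 0, noise$usTextureSd),
                      nax, nlat)
    fr <- array(0, dim = c(nax, nlat, length(tUs)))
    for (f in seq_along(tUs)) {
      img <- texture
      for (b in names(bands))
        img[bands[[b]], ] <- img[bands[[b]], ] + noise$usGain * actUs[f, b]
      if (noise$usNoiseSd > 0)
        img <- img + matrix(rnorm(nax * nlat, 0, noise$usNoiseSd), nax, nlat)
      fr[, , f] <- pmin(pmax(round(img), 0), 255)
    }
    us <- new("UltrasoundSequence", frames = fr,
              frameRateHz = geometry$frameRateHz,
              pixelSpacingMm = rep(geometry$pixelSpacingMm, 2),
              timeOriginS = 0)

    latent <- list(time = tKin, activations = actScaled,
                   strideScales = scales, latentNames = lm,
                   view = geometry$view)

    new("SyntheticTrial", task = template@task, kinematics = kin, emg = emg,
        ultrasound = us, heelStrikes = hs, latent = latent,
        template = template, seed = as.integer(seed))
  })
}

## central-difference gradient with one-sided ends
numGradient <- function(x, dt) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g
}

#' Dataset configuration for a full synthetic study
#'
#' Defaults: one trial per ambulation task, with 15 strides for each of
#' the three walking tasks and 8 / 10 strides for stair ascent / descent
#' (the cohort's mean stair-stride counts), so walking strides outnumber
#' stair strides as they do in treadmill protocols.
#'
#' @param tasks ambulation tasks to simulate.
#' @param stridesPerTask named integer vector of strides per task.
#' @param noise a [noiseConfig()] list.
#' @param geometry a [usGeometry()] list.
#' @return named list.
#' @export
datasetConfig <- function(tasks = TASKS,
                          stridesPerTask = c(level_walk = 15L,
                                             incline_walk = 15L,
                                             decline_walk = 15L,
                                             stair_ascent = 8L,
                                             stair_descent = 10L),
                          noise = noiseConfig(),
                          geometry = usGeometry()) {
  if (length(tasks) == 0L)
    stopNamed("myofuse_invalid_argument", "task list must not be empty")
  if (!all(tasks %in% TASKS))
    stopNamed("myofuse_unknown_task", "unknown task label in task list")
  list(tasks = tasks, stridesPerTask = stridesPerTask[tasks],
       noise = noise, geometry = geometry)
}

#' Generate the full multi-task synthetic dataset
#'
#' One [generateTrial()] per configured task, with per-task child seeds
#' derived from `seed`. Identical `(cfg, seed)` pairs reproduce the
#' dataset bit-identically.
#'
#' @param cfg a [datasetConfig()] list.
#' @param seed integer RNG seed.
#' @return named list of [SyntheticTrial-class], one per task.
#' @export
generateGaitDataset <- function(cfg = datasetConfig(), seed = 1L) {
  trials <- lapply(seq_along(cfg$tasks), function(i) {
    task <- cfg$tasks[i]
    tpl <- makeGaitTemplate(task, seed = childSeed(seed, i))
    generateTrial(tpl, nStrides = cfg$stridesPerTask[[task]],
                  noise = cfg$noise, geometry = cfg$geometry,
                  seed = childSeed(seed, 100L + i))
  })
  names(trials) <- cfg$tasks
  trials
}
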