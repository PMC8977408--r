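---
title: "Methods: multimodal muscle sensing, Gaussian process regression and stride-wise validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal muscle sensing, Gaussian process regression and stride-wise validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myofuse)
```

## The estimation problem

Powered lower-limb assistive devices need a continuous, multi-joint
readout of user intent. Surface electromyography (EMG) measures the
electrical activity of superficial muscles and precedes motion, but it
is blind to deep muscles and captures only one determinant of force.
Sonomyography (SMG) — B-mode grayscale ultrasound of skeletal muscle —
images the deformation of both superficial and deep muscle tissue at a
much higher spatial dimensionality. `myofuse` implements a task-invariant
pipeline that maps features of either modality, or their fusion, to six
kinematic targets — hip, knee and ankle angle (degrees) and angular
velocity (deg/s) — during five ambulation tasks (level, incline and
decline walking, stair ascent and descent), with Gaussian process
regression (GPR) and leave-one-stride-out cross-validation.

## Sensor features

**EMG.** Raw 8-channel EMG at 1,200 Hz is de-offset per channel and
band-passed 20–450 Hz with a zero-phase Butterworth filter of design
order 4 (`preprocessEmg()`). On sliding windows of 200 ms advanced by
50 ms (i.e. 150 ms overlap, a 20 Hz stream), six features per muscle are
computed (`extractEmgFeatures()`): mean absolute value (MAV), zero
crossings (ZC), slope sign changes (SSC), waveform length (WL), and the
first two coefficients of a 4th-order autoregressive (AR) model — 48
features per time point for 8 muscles.

Two places in this definition were genuinely open and are fixed as
follows:

* *Window advance.* A 200 ms window with "50 ms overlap" would produce a
  ~6.7 Hz stream; we take the 20 Hz feature rate as definitive, so
  windows advance by 50 ms and overlap by 150 ms.
* *AR estimator.* The AR coefficients are estimated by the Burg method
  (`stats::ar.burg`), which is stable on 240-sample windows, under the
  convention \(x_t \approx \sum_k a_k x_{t-k}\). The ZC/SSC deadband
  defaults to 0 and is exposed as a parameter. Timestamps use the
  window-end convention so the stream is causal.

**SMG.** Each grayscale frame is reduced to mean intensities of
non-overlapping 3 × 3 mm blocks (`blockMeanIntensity()`), anchored at
the superficial-left corner with trailing partial blocks discarded, and
flattened row-major from superficial to deep (`flattenBlocks()`).
Temporal features are the per-block time derivative between consecutive
frames (intensity/s); the first frame's temporal features are zero so
frames and feature rows stay aligned. Under the default geometry —
60 mm axial (a typical anterior-thigh penetration depth) × 39 mm lateral
at 0.5 mm/pixel, i.e. a 20 × 13 block grid — this yields 520 features
per frame (`extractSmgFeatures()`). The lateral extent is
reverse-engineered from that published feature count; both the geometry
and the block size are configurable.

## Synchronisation, fusion, strides

All streams are aligned on the EMG feature clock (20 Hz), the lowest
feature rate (`alignStreams()`): SMG features by nearest frame time
(ties to the earlier frame), kinematics by linear interpolation (at
100 Hz input the interpolation error is negligible relative to the
targets). Fusion is column-wise concatenation of the SMG and EMG
feature matrices — the minimal faithful reading of "fusion of features
from both sensing modalities". Rows are segmented into strides at heel
strikes, `[hs_i, hs_{i+1})` (`segmentStrides()`); strides shorter than
4 clock ticks are dropped with a warning. Heel strikes are taken as
given (from the generator's ground truth or an events file): gait-event
detection is out of scope. `buildPooled()` concatenates all tasks into
one stride-labelled dataset per modality; standardisation is *not*
computed there — it is a fitting-time contract evaluated per
cross-validation fold from training rows only.

## The regression model

For each kinematic target and modality an independent GPR is fitted,

$$ f(x) \sim \mathcal{GP}(m(x),\, k(x, x')), \qquad
   k(x,x') = \sigma^2 \Big(1 + \frac{r^2}{2\alpha l^2}\Big)^{-\alpha},
   \quad r^2 = (x-x')^\top (x-x'), $$

the rational quadratic kernel: a scale mixture of squared-exponential
kernels with amplitude \(\sigma\), mixture parameter \(\alpha > 0\) and
length-scale \(l\) (\(\alpha \to \infty\) recovers the squared
exponential). The mean function is the constant training-target mean —
zero after target standardisation — which is the conventional default
when no trend model is specified. Observation noise \(\sigma_n\) is a
fitted hyperparameter.

Hyperparameters are fitted by maximising the log marginal likelihood
with analytic gradients on the log-parameter scale (L-BFGS-B,
multi-restart, seeded). The optimizer honours a gradient tolerance and
step tolerance of 10^-3 and an iteration cap, and a *block size* of
1,000 observations: above that training-set size the likelihood is
evaluated on a seeded subset of block-size rows. Prediction is always
exact dense inference on the full training set,

$$ \hat y_* = m + k(X_*, X)\,(K + \sigma_n^2 I)^{-1} (y - m), $$

de-standardised to output units. A relative diagonal jitter of 10^-8
keeps the Cholesky factorisation stable in the noise-free limit;
`fitGpr()` accepts fixed `KernelParams` to skip the optimisation.

Numerical notes: length-scale initialisation at the median pairwise
training distance; restart jitter is seeded; box bounds keep
\(\log\alpha \in [\log 10^{-3}, \log 10^{3}]\) and
\(\sigma_n \ge 10^{-4}\); a degenerate (zero-variance) target is a named
error; non-convergence returns a model with the `converged` flag unset
rather than failing.

## Cross-validation and metrics

Leave-one-stride-out, task-invariant (`losoFolds()`): fold *i* tests the
*i*-th stride of every task that has at least *i* strides, so with
unequal stride counts later folds simply carry fewer test strides;
across folds every stride of every task is the test stride exactly
once. Per fold, feature/target standardisation and the hyperparameter
subset are computed from training rows only; `runExperiment()` records
a per-fold audit (train/test disjointness, standardisation provenance)
that `auditReport()` re-verifies.

Metrics per (modality, target, task): RMSE; range-normalised RMSE
(percent of the measured range of that task's test rows); and adjusted
\(R^2 = 1 - \frac{N-1}{N-1-p}(1 - R^2)\) with
\(R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}\), where \(N\) is the (mean
per-fold) training-row count and \(p\) the number of feature columns of
the modality (48, 520 or 568). Per-task cells aggregate all test
strides of the task before computing RMSE, and the "overall" row is the
unweighted mean of the five task values (adjusted \(R^2\) overall is
computed on the pooled predictions). When \(N - 1 - p \le 0\) the
adjustment is undefined and the cell is reported as `NA`.

Across-replicate modality comparison (`compareModalities()`): one-way
ANOVA on per-replicate overall RMSE (each replicate standing in for one
subject), followed — only when the group effect is significant at
\(\alpha = 0.05\) — by unequal-n Tukey–Kramer pairwise comparisons via
the studentized-range distribution.

## The synthetic-data generator

No subject recordings ship with the package; `generateGaitDataset()`
produces multimodal trials with known latent ground truth that have the
statistical structure the analysis assumes:

* **Kinematics.** Per task, smooth stride-periodic joint profiles
  (truncated Fourier series rescaled to physiologic, task-specific
  ranges; knee excursions differ across tasks by construction), sampled
  on a phase clock with 5% SD stride-duration jitter, plus 0.5° SD
  measurement noise. Angular velocity is the numerical time-derivative
  of the *noisy* angle — deliberately, since velocity obtained by
  differentiating motion-capture data is noisy in exactly this way.
* **Latent muscle states.** Eleven latent activations (8 EMG-recorded
  muscles plus VM, VI and ST, which only ultrasound can see) follow
  non-negative periodic bumps of gait phase, scaled per stride by
  log-normal factors (15% SD). A joints × latents coupling matrix maps
  stride-level activation excess onto joint-angle deviations (3° per
  unit excess by default). Every joint is coupled to at least one
  EMG-only and one SMG-only latent, so neither modality alone carries
  all stride-level information — this designed dependency structure is
  what makes fusion genuinely more informative, and it is asserted by
  the tests. The ST/VI couplings to hip and ankle are a construct of
  this design (guaranteeing single-modality-blind variance at every
  joint), not a biomechanical claim.
* **EMG.** Channel \(m\) is \(a_m(\phi(t))\) × band-limited (20–450 Hz)
  unit-variance Gaussian noise × gain, plus a small instrumentation
  noise floor — the standard phenomenological surface-EMG model, which
  reproduces the envelope–activation relationship the features exploit
  without simulating motor units.
* **Ultrasound.** Frames are a static speckle-like texture (per-pixel
  Gaussian, SD 12 gray levels around a baseline of 90) plus
  `usGain` (60) gray levels per unit activation in horizontal muscle
  bands (anterior: RF/VM/VI thirds; posterior: BF/ST halves), plus
  per-frame noise, rounded and clipped to [0, 255]. The frame rate
  defaults to 20 Hz so frames align one-to-one with the EMG feature
  clock; the true acquisition rate of such scanners is configurable.

What the generator does **not** emulate: speckle physics, probe motion
and out-of-plane artifacts, muscle architecture (fascicles, pennation),
electromechanical delay, crosstalk between EMG channels, and
subject-specific anthropometry. Passing tests therefore demonstrate the
pipeline's correctness and the designed information structure, not
clinical performance on human recordings.

`zeroNoiseConfig()` switches off every configurable stochastic element
(measurement noise, jitter, stride scaling); the EMG carrier remains
stochastic because EMG *is* modulated noise. Under zero noise the
mapping from latent activation to band intensity is exactly monotone,
and fusion models recover all six targets nearly perfectly — the
recoverability check.

## Study sizes and defaults

Defaults are desk-scale study conditions chosen once: 15 strides per
walking task and 8 / 10 stair ascent / descent strides (stair counts
matching typical protocol yields), one trial per task, giving ~1,800
pooled 20 Hz rows and 15 cross-validation folds. The replicate study
used for modality comparisons runs 10 seeds at 4/4/4/3/3 strides per
task so that a two-modality, three-target comparison stays cheap; the
fold-wise hyperparameter search in `runExperiment()` uses a 400-row
seeded subset, one restart and a 40–60 iteration cap, which on these
data reaches the same optima as the heavier `fitGpr()` defaults. All
sizes are configurable, and every random element is seeded.

## Known limitations

* Fusion is feature concatenation; no learned weighting or alignment.
* One independent GP per target; no multi-output coupling.
* Heel strikes must be supplied; no gait-event detection.
* The adjusted-\(R^2\) penalty uses the raw feature count \(p\), which
  is conservative for kernel models whose effective degrees of freedom
  are smaller.
* Real-time/online operation is out of scope; the pipeline is offline.
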