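Package: myofuse
Title: Multimodal EMG-Sonomyography Fusion for Continuous Lower-Limb
    Kinematic Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Task-invariant estimation of hip, knee and ankle angles and
    angular velocities from wearable muscle sensing. Implements
    time-domain feature extraction for multi-channel surface
    electromyography (mean absolute value, zero crossings, slope sign
    changes, waveform length and autoregressive coefficients on sliding
    windows), intensity-based feature extraction for B-mode ultrasound
    (sonomyography) frame sequences, synchronisation and fusion of the
    two feature streams with motion-capture kinematics, Gaussian process
    regression with a rational quadratic kernel, and a
    leave-one-stride-out cross-validation harness with RMSE,
    range-normalised RMSE, adjusted R-squared and ANOVA/Tukey-Kramer
    modality comparisons. A synthetic gait generator with known latent
    muscle states provides fully reproducible multimodal trials for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    tiff,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'synthetic.R'
    'emg.R'
    'smg.R'
    'fusion.R'
    'gpr.R'
    'metrics.R'
    'evaluate.R'
    'io.R'
    'myofuse-package.R'
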