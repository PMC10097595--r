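Package: gazemri
Title: Cameraless MR-Based Eye Tracking with a 3D Convolutional Decoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes on-screen gaze position (and eyes-open/closed state) from
    the multivoxel magnetic-resonance signal of the eyeballs. Implements a 3D
    convolutional regression network with residual blocks, group normalization,
    mish activations, replicated sub-TR output heads and an unsupervised
    predicted-error (confidence) head, trained with a combined Euclidean-error
    and error-prediction loss. Includes eye-mask handling and the two-stage
    (temporal median/MAD, spatial z-score) voxel normalization, gaze-label
    preparation from camera traces, three cross-validation schemes, training-set
    subsampling and label-shift harnesses, decoding-quality metrics (Euclidean
    error, Pearson r, R-squared, fraction of stimulus size), predicted-error
    based reliability filtering, sub-TR temporal super-resolution analysis,
    eyes-closed classification, slice-shuffling saliency maps, and construction
    of gaze-derived fMRI nuisance regressors (far/short eye-movement regressors
    with canonical double-gamma HRF convolution). A synthetic eyeball-phantom
    generator makes every stage testable without real imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
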