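Package: rebold
Title: Recurrent and Ridge Encoding Models for Continuous-Design fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise encoding response models for time-continuous fMRI
    experiments (movie watching and similar naturalistic designs). Implements
    the feedforward ridge-regression family with hemodynamic-response-function
    (HRF) basis sets (canonical HRF, its temporal and dispersion derivatives,
    and finite-impulse-response lags), a recurrent family of two-layer LSTM and
    GRU networks with per-voxel linear readouts trained by truncated
    backpropagation through time, estimation of voxel-specific HRFs by impulse
    stimulation of any trained response model, statistical evaluation
    machinery (cross-validated correlation, Monte-Carlo noise ceilings,
    permutation tests, bootstrap model comparison), representational
    dissimilarity and optimal-lag analyses of model internals, Gabor-energy
    spatial-envelope stimulus features, and a synthetic block-structured
    dataset generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
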