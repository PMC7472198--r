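Package: braingp
Title: Full-Brain Correlation Models and Gaussian Process Reconstruction
    of Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Learns a full-brain correlation model from multiple patients'
    sparse intracranial (ECoG/iEEG) recordings by radial basis function
    weighted averaging of Fisher z-transformed interelectrode correlations,
    and reconstructs z-scored voltage time series at arbitrary unobserved
    brain locations through the Gaussian-process conditional expectation.
    Includes the accompanying preprocessing pipeline (notch filtering,
    resampling, kurtosis-based channel and patient exclusion, per-session
    z-scoring), leave-one-electrode-out cross-validation within and across
    patients, narrowband and broadband spectral derivatives, electrode
    density and information-score maps on an MNI-aligned voxel grid, and a
    synthetic multi-patient generator with known ground-truth correlation
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    MASS,
    RNifti,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
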