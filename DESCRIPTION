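Package: breathCVR
Title: Quantitative Cerebrovascular Reactivity Mapping from Breath-Hold BOLD fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping cerebrovascular reactivity (CVR) amplitude
    (%BOLD/mmHg) and hemodynamic delay (s) from breath-hold BOLD fMRI when
    end-tidal CO2 recordings are of variable quality. Implements end-tidal
    CO2 extraction and respiration-volume-per-time (RVT) computation from
    raw physiological traces, per-trial breath-hold quality grading,
    temporal alignment and min-max rescaling of surrogate regressors to
    mmHg using one to three high-quality breath-hold blocks, a 1D
    fully-convolutional network that predicts normalized end-tidal CO2
    from RVT, voxelwise lagged-GLM estimation of CVR amplitude and delay,
    comparison metrics for regressors and maps, and a synthetic
    physiology/BOLD-phantom generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
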