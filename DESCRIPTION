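Package: huttdot
Title: Regional Diffuse Optical Tomography Analysis of Cerebral Oxygenation
    During the Head-Up Tilt Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for regional analysis of prefrontal
    cerebral oxygenation during the head-up tilt table test (HUTT) measured
    with continuous-wave diffuse optical tomography (DOT). Converts raw
    multi-distance two-wavelength optical intensities to optical density and
    hemoglobin concentration changes (modified Beer-Lambert law, low-pass
    filtering, moving-average smoothing, wavelet-based motion-artifact
    removal), reconstructs voxel images with an analytic semi-infinite-medium
    forward model and spatially variant Tikhonov regularization, averages
    images over six frontal-gyrus regions, extracts rate-of-oxyhemoglobin-
    change features over the dynamic-to-static tilt window, computes
    pointwise group-difference and left-right laterality statistics, and
    classifies orthostatic-intolerance subgroups of Parkinson's disease
    patients with a bagged ensemble of decision trees (out-of-bag accuracy
    and permuted-delta-error feature importance). A calibrated synthetic
    cohort generator makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    MASS,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    randomForest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
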