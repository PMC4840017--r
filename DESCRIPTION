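Package: nirstopo
Title: Sensor-Space Topographic Group Analysis for fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level statistical analysis of multi-channel functional
    near-infrared spectroscopy (fNIRS) recordings in sensor space.
    Converts optical-density changes to hemoglobin concentration changes
    via the modified Beer-Lambert law, performs temporal preprocessing
    (motion-artifact reduction, physiological band-stop filtering, DCT
    high-pass, downsampling) and AR(1)-prewhitened general linear model
    fits per subject, interpolates channel-wise contrast estimates onto
    canonical 2D and 3D scalp surfaces (piecewise-linear interpolation
    with Gaussian smoothing on a regular grid; spherical splines on a
    triangulated sphere), and carries the per-subject contrast images to
    a summary-statistics random-effects group model with family-wise
    error control by Bonferroni correction over channels or by random
    field theory over the scalp search region (peak and cluster level).
    Includes a synthetic multi-subject data generator with known ground
    truth for validation, readers and writers for SNIRF-style HDF5
    containers, tabular time series, NIfTI-1 and GIfTI images, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    deldir,
    RNifti,
    rhdf5,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
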