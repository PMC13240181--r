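Package: wetspr
Title: Water-Equivalent Thickness Estimation and Stopping-Power Prediction
    from Dual-Energy CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Slice-wise estimation of the water-equivalent thickness (WET)
    of scanned objects from CT images using three thickness estimation
    methods (a maximum-attenuation-extent method and two whole-slice
    attenuation-area methods), size-dependent dual-energy CT calibration of
    electron-density and effective-atomic-number weighting factors,
    voxel-wise stopping-power-ratio (SPR) prediction via the Bethe
    equation, and a sensitivity analysis propagating WET variability into
    SPR deviations.  Includes a synthetic phantom generator (ellipses,
    cylindrical insert phantoms, patient couch, parametric beam-hardening
    bias) with analytic ground-truth WET oracles, plus minimal readers and
    writers for single-frame CT DICOM series and a plain-text matrix
    fixture format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'imaging-core.R'
    'dicom.R'
    'phantoms.R'
    'tem.R'
    'calibration.R'
    'spr.R'
    'sensitivity.R'
    'pipeline.R'
    'wetspr-package.R'
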