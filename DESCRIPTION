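Package: photoresp
Title: Photogrammetric Thoracoabdominal Volumetry and Lung Volume Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based photogrammetric analysis of forced-breathing
    maneuvers in supine subjects. Detects five circular adhesive markers in
    video frames taken at maximal expiration and maximal inspiration,
    calibrates pixel scale from the known 13 mm marker diameter, partitions
    the sagittal trunk profile into upper/lower thorax and abdomen
    compartments, extrudes compartment areas by the caliper-measured thorax
    length into volumes, and derives the total volumetric mobility
    (inspiration minus expiration thoracoabdominal volume). Ships reference
    regression equations predicting forced vital capacity and deep
    inspiration from height, thorax length and mobility, supports refitting
    the same model form on new cohorts, and provides the validation
    statistics layer (Pearson correlations, Bland-Altman agreement, cohort
    summaries). Includes a synthetic-data generator producing subjects,
    ground-truth marker kinematics and rendered frames so the whole pipeline
    is testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
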