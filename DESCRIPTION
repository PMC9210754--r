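Package: fogrec
Title: Freezing-of-Gait Recognition from Wearable Multi-Sensor Gait Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Window-level detection of freezing-of-gait (FoG) episodes in
    Parkinson's disease from lower-body wearable sensors (triaxial
    accelerometers and gyroscopes at seven body sites plus six plantar
    force-sensing resistors). Provides a synthetic cohort generator that
    emulates 100 Hz gait recordings with locomotor-band walking and
    trembling-band freezing signatures, missing-sample interpolation and
    linear-phase FIR band-pass preprocessing, sliding-window segmentation
    with 13 per-channel time/frequency/statistical features including the
    freeze index, filter feature ranking by one-way ANOVA F or mutual
    information, SMOTE minority oversampling, and random-forest
    classification evaluated by leave-one-subject-out cross-validation,
    including sensor-configuration and top-k feature-count experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
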