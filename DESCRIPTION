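Package: tissuefp
Title: Tissue Fingerprinting from H&E Images: Patient Matching and
    Receptor-Status Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns stain-style-invariant "tissue fingerprints" -- fixed-length
    feature vectors from a convolutional network trained to recognise which
    patient a histology patch came from -- and reuses them downstream. Provides
    a synthetic H&E-like cohort generator (tissue-microarray cores in two site
    styles, whole-slide mosaics with tissue-type masks and texture-coupled
    marker labels), core preparation and patch sampling, the composite identity
    loss (cross entropy plus a normalized fingerprint-distance penalty), the
    left/right half matching game with core- and patient-level accuracies,
    a multiple-instance head for patient-level ER/PR/Her2-style marker
    prediction with cross-validation and early stopping, and heatmap and
    2-D embedding visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
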