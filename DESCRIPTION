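Package: carrotmorph
Title: Automated Shoot and Root Morphometrics for Carrot Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Image-based phenotyping of whole carrot plants photographed on a
    white baseboard with a black divider line separating shoot from storage
    root. Segments each photograph into shoot and root masks, computes
    crown-anchored radial shoot biomass profiles and row-sum root biomass
    profiles, extracts classic region morphometrics, predicts petiole width,
    number, and length with regression models trained on ground-truth tables,
    runs population-level shape principal components analysis with eigenvector
    sweeps, and provides repeatability (variance-component) and QTL-support
    statistics (percent variance explained from LOD scores, support-interval
    widths). A procedural generator of carrot-like plant images with full
    ground-truth metadata makes every stage testable without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    lme4,
    nnet,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
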