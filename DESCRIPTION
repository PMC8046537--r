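Package: hkls
Title: Hybrid Hierarchical K-Means and Level-Set Segmentation of
    Melanocytic Skin Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage segmentation of melanocytic skin lesions in
    dermoscopic and standard clinical photographs.  Preprocessing builds an
    illumination-robust fusion image from histogram-equalized CIELAB
    chromaticity channels and suppresses hair, ruler and vignetting
    artifacts; a two-level hierarchical K-means clustering estimates an
    initial lesion contour; distance-regularized level-set evolution
    (DRLSE) with a double-well regularization potential refines the fine
    border.  Includes morphological postprocessing with Delaunay-based
    boundary smoothing, segmentation agreement statistics (Dice, Jaccard,
    F-measure, Hausdorff distance, Bland-Altman limits of agreement, area
    regression), and a seeded synthetic dermoscopy image generator so the
    whole pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
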