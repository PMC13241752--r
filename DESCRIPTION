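Package: periwound
Title: Wound Edge Morphometry from Photographs, Masks and Depth Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of chronic-wound edge morphology from clinical
    photographs paired with binary wound masks and monocular depth maps.
    The peri-wound transition band is standardised into a common geometric
    frame by resampling along contour normals (rectification), depth-derived
    edge profiles are extracted and summarised by trend templates (flat,
    linear, abrupt, smooth), and geometric plus visual descriptors are
    computed per wound. Includes a parametric synthetic wound generator with
    five edge-morphology archetypes and simulated raters, chance-corrected
    agreement statistics (Cohen's kappa, Adjusted Rand Index, optimal label
    matching), and unsupervised and supervised experiments comparing
    geometry-only against full-feature wound edge classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    tiff,
    minpack.lm,
    xgboost,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
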