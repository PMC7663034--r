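Package: gmNodule
Title: Geometric and Morphological Feature Analysis of Thyroid Nodule
    Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts 27 geometric and morphological shape descriptors
    (convexity, solidity, compactness, radial variances, axis-based and
    perimeter-ratio features) from closed thyroid-nodule boundary contours
    in ultrasound images, applies a fixed TIRADS-motivated selection of 11
    clinically significant features, balances benign/malignant cohorts by
    stochastic flip/rotate/blur augmentation, and trains and evaluates a
    random-forest benign-versus-malignant classifier reporting accuracy,
    sensitivity and specificity. Ships a seeded synthetic nodule-shape
    generator so the whole pipeline runs without any image download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    mgcv,
    ranger,
    xml2,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
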