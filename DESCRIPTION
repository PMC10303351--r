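Package: fundushsi
Title: Hyperspectral Artery-Vein Analysis of Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for pixel-level artery-vein classification in retinal
    fundus photographs via simulated hyperspectral imaging. Segments
    retinal vessels with an oriented Gabor filter bank followed by
    iterative-mean binarization and small-object removal, reconstructs a
    per-pixel visible reflectance spectrum (380-780 nm) from camera RGB
    using a 24-patch color-checker calibration and a six-eigenvector
    principal-component basis, and separates arteries from veins by
    thresholding min-max normalized principal-component scores.
    Includes a synthetic fundus-phantom generator with stage-controlled
    artery-vein spectral contrast emulating diabetic-retinopathy
    progression, and pixel-level sensitivity/precision/F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    generics,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
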