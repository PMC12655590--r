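Package: tomatopheno
Title: Tomato Fruit Section Phenotyping from RGB-D Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated phenotyping pipeline for sectioned tomato fruits
    imaged with a top-view RGB-D camera. Provides fruit isolation and tiling
    from tray images, a linear-attention hierarchical transformer
    (SegFormer-MLLA) for stem-scar and locule segmentation with hybrid
    cross-entropy/Dice training, a hybrid parametric plus random-forest depth
    calibration model for time-of-flight sensor bias, metric conversion via
    camera intrinsics, and extraction of twelve phenotypic traits (diameters,
    shape index, stem-scar width and depth, locule count and areas, mesocarp
    thickness, mesocarp and locule color). A synthetic section renderer with
    exact ground truth supports testing and calibration end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    png,
    randomForest,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
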