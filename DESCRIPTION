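Package: stereophyte
Title: Stereo Image Phenotyping of Grapevine Canopies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-based field phenotyping of grapevine from rectified RGB
    stereo pairs. Dense depth maps are reconstructed by globally optimizing a
    convex functionally lifted stereo energy with anisotropic total-variation
    regularization; depth and color classifiers segment each pixel into
    background, leaf, stem, or grape via a relaxed Potts model; depth-weighted
    3D surface areas yield digital leaf areas and fruit-to-leaf ratios.
    Includes epipolar rectification from feature matches, a synthetic stereo
    scene generator with analytic ground truth, growth-series aggregation and
    validation statistics (confusion matrices, leaf-area regression, RMSE and
    residual bounds).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jpeg,
    png,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
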