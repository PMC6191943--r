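Package: histoquant
Title: Trainable Marker Segmentation and Spatial Quantification for Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A trainable pipeline for histochemical and immunohistochemical
    (HC/IHC) slide images. Segments the tissue region by heavy smoothing and
    Otsu thresholding, classifies stain-specific marker pixels with a stacked
    cost-sensitive classifier (two decision trees, an RBF support vector
    machine and a K-nearest-neighbour layer) trained with hard-negative
    mining, quantifies marker density and spatial distribution through
    minimum-distance histograms, registers serial tissue sections by tissue
    shape, and measures marker co-existence through automatically extracted
    concentration regions. Includes a synthetic fixture generator producing
    histology-like images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    rpart,
    e1071,
    class,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
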