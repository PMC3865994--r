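Package: pombeseg
Title: Robust Segmentation of Fission Yeast Cells in Bright-Field Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments rod-shaped fission yeast (Schizosaccharomyces pombe)
    cells from transmitted-illumination (bright-field) microscopy images that
    suffer from focus gradients and variable contrast. Nuclear-fluorescence
    channels, when available, guide an adaptive focus-gradient correction that
    complements negatively defocused image regions about the background mean
    and normalises contrast. Pixels are then classified into background, cell
    interior, cell membrane and ambiguous classes by adaptive (Otsu)
    thresholds; ambiguous pixels are resolved by an iterative
    distance-transform region-growing procedure. Initial contours from
    interior components are evolved under gradient-vector-flow (GVF) snake
    forces to the final cell boundaries, and a machine-learning validation
    stage (RBF-kernel support vector machines plus a classification tree)
    removes merged, partial and artifactual contours. A synthetic scene
    generator with ground-truth masks supports testing and validator training
    without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    e1071,
    rpart,
    igraph,
    mgcv,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
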