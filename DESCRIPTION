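Package: grainclass
Title: Morpho-Colorimetric Phenotyping and Neural-Network Classification
    of Rice Grains from Color Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for grain-by-grain phenotyping of rice from color
    images captured over a contrasting background. Segments individual
    grains (Otsu binarization, morphological cleanup and distance-transform
    watershed splitting of touching kernels), extracts nine dimensionless
    morpho-colorimetric descriptors per grain (box-counting fractal
    dimension, circularity, aspect ratio, extent, area-perimeter ratio
    index, CIELab L/a/b and yellowness index), and classifies grains into
    15 commercial rice classes with a two-layer feedforward network trained
    by Levenberg-Marquardt with Bayesian regularization. Includes a
    synthetic scene renderer with analytic ground truth for validation,
    descriptive statistics (one-way ANOVA with Tukey-Kramer letters, PCA,
    hierarchical clustering of class means), and an end-to-end deployment
    pipeline producing annotated decision images and evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    nnet
Config/testthat/edition: 3
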