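Package: leafspec
Title: Hyperspectral Classification of Herbicide Stress in Rice Seedlings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ground-based visible/near-infrared hyperspectral image analysis
    for plant stress phenotyping. Reads and writes ENVI-style reflectance
    cubes, calibrates raw intensity against dark and white references,
    segments vegetation pixels, denoises pixel spectra with a Daubechies-9
    wavelet approximation and moving-average smoothing, extracts principal
    component score images and features, trains one-vs-one soft-margin
    support vector classifiers with a radial basis function kernel via a
    from-scratch SMO solver with decade grid search over cost and kernel
    width, and evaluates models with confusion matrices, accuracy, Cohen's
    kappa and pixel-wise prediction maps. A synthetic-scene generator with
    treatment-structured vegetation reflectance makes the full pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    jsonlite
Config/testthat/edition: 3
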