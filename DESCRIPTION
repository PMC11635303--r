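Package: canopylai
Title: Leaf Area Index Estimation from Hyperspectral Canopy Imagery with
    Spectral and Haralick Texture Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for estimating potato leaf area index (LAI)
    from very-high-resolution hyperspectral canopy imagery. Simulates a
    treatment-structured field trial (plot layout, disc-weighing ground truth,
    125-band reflectance cubes); extracts three spectral feature families
    (band reflectance, first-order differential spectra, 30 vegetation
    indices) and 28 Haralick texture features (GLCM simple and advanced,
    gray-level run-length higher-order) from the first principal-component
    image; selects minimally collinear feature subsets with the successive
    projections algorithm; and fits and evaluates partial least squares,
    random forest, and Gaussian process regressions with a replicate-based
    calibration/validation split, including per-pixel LAI map production.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
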