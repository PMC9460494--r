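Package: kapurseg
Title: Optimization-Driven Multilevel Thresholding Segmentation for
    Grayscale Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilevel histogram segmentation of 8-bit grayscale (MR-like)
    images by Kapur-entropy maximization driven by swarm and evolutionary
    optimizers (artificial bee colony, particle swarm and its fuzzy and
    Darwinian variants, genetic algorithm), fuzzy pseudo trapezoid-shaped
    soft thresholding with defuzzification, and equal-area multi-Otsu and
    K-means baselines. Includes deterministic Gaussian, speckle,
    salt-and-pepper and Rician noise generators with graded intensity
    sweeps, label-map quality metrics (global SSIM, Pearson correlation,
    SNR, MSE) scored against each method's own noise-free segmentation,
    Wilcoxon and chi-square significance testing, synthetic phantoms with
    known cartilage-ribbon geometry, and morphological feature extraction
    (area, Sobel perimeter, skeleton length).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    nortest,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
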