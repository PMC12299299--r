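Package: uriquant
Title: Quantitative Analysis of Urine Dipstick Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantification of urine test-strip (dipstick)
    colorimetry: synthetic strip-image generation, a classical image
    processing chain (Gaussian smoothing, highlight suppression, Otsu
    thresholding, morphology, edge-based pad localization) that extracts a
    mean RGB per reagent pad, device color correction by per-channel
    polynomial regression in CIELab, semi-quantitative level matching
    against a colorimetric card, Kubelka-Munk / Beer-Lambert reflectance
    relations, printed concentration-to-RGB calibration curves for urinary
    protein and leukocytes, and concentration prediction with a
    backpropagation neural network whose initial weights and thresholds are
    found by the whale optimization algorithm (with particle swarm and
    genetic algorithm baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
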