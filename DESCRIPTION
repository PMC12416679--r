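Package: hyperstack
Title: Focus Stacking, Color Calibration and Resolution Analysis for
    Non-Contact Dermoscopy Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes stacks of differently-focused dermoscopy frames into a
    single color-calibrated, all-in-focus image. Implements thin-lens focal
    sweep planning, non-local means denoising, color-chart calibration by
    linear, polynomial and k-means-clustered regression with RGB and CIELab
    color distances, enhanced-correlation-coefficient (ECC) stack alignment,
    Laplacian-variance focus measurement, weighted multifocus fusion, four
    fusion-quality metrics (normalized mutual information, spatial frequency
    error, Yang's SSIM, Chen-Varshney index), and an objective USAF 1951
    resolution analysis based on smoothed intensity profiles and an
    extrema-pattern criterion. A seeded synthetic-scene generator renders
    defocus-blurred, magnification-drifted, noisy stacks plus color charts
    and tri-bar targets so the whole pipeline is testable without hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
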