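Package: symfbp
Title: Quadrant-Symmetry Accelerated Fan-Beam Filtered Back-Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for two-dimensional fan-beam tomographic image
    reconstruction with a quadrant-symmetry accelerated weighted
    back-projection. Provides analytic ellipse phantoms and a fan-beam
    forward projector so the reconstruction chain is fully testable
    without external data, a reference (naive) and a symmetry-accelerated
    back-projector with instrumented operation counters, image-quality
    metrics (MSE, PSNR, global SSIM), summary-statistic trial statistics
    (incidence from an ordinal grading table, 2x2 chi-squared test,
    two-sample t test), plain-text image and sinogram formats, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
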