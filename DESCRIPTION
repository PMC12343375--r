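Package: varangio
Title: Digital Variance Angiography Simulation and Contrast-to-Noise Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for forming digital variance angiography (DVA) and digital
    subtraction angiography (DSA) images from the same raw angiographic frame
    series, and for comparing their image quality. Includes a synthetic
    angiographic phantom generator with known ground truth (vessel geometry,
    gamma-variate bolus kinetics, Poisson photon noise, rigid patient motion),
    pixel-shift motion correction by subpixel spectral cross-correlation,
    paired-ROI contrast-to-noise ratio (CNR) measurement, and the
    nonparametric statistical battery used in DVA-versus-DSA reader studies
    (Wilcoxon signed-rank, one-sample t, Monte-Carlo Kolmogorov-Smirnov
    normality, Kendall's coefficient of concordance, simulation-based power).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
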