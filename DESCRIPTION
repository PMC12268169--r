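Package: ricsbind
Title: Raster Image Correlation Spectroscopy Analysis of Transcription
    Factor Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates nuclear concentration, immobile fraction and
    chromatin-correlated ("active") fraction of fluorescently tagged
    transcription factors from two-channel confocal raster-scan movies by
    raster image correlation spectroscopy (RICS) and cross-correlation RICS
    (ccRICS), and links the resulting concentration pools through a
    thermodynamic equilibrium binding model with Hill and power-law site
    capacities. Includes a Brownian-dynamics raster-scan image simulator with
    known ground truth (diffusing, quasi-immobile and co-bound species
    rendered through a 3D Gaussian point spread function with analog detector
    noise), watershed-based nuclear segmentation, masked FFT spatial
    correlation with exact pairwise-count normalization, two-step ACF model
    fitting, bead z-stack channel registration, molecular brightness and
    detector S-factor analysis, and Smoluchowski residence-time calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    mclust,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
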