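Package: bcdgeom
Title: Embryo Geometry and the Bicoid Morphogen Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of how embryo geometry shapes the Bicoid
    (Bcd) anterior morphogen gradient in Drosophila. Provides dual
    distance systems on midsagittal embryo outlines (projected
    anterior-posterior distance versus contour distance along the dorsal
    or ventral perimeter), a sliding-window cortical intensity extraction
    pipeline, exponential gradient and Hill input-output fitting, intensity
    noise and positional-error analysis, iso-concentration contour and
    target-boundary slant statistics, a synthetic embryo cohort generator
    with known ground truth, and a 3-D nuclear-cycle reaction-diffusion
    simulator of gradient formation on asymmetric semi-ellipsoid embryos.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
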