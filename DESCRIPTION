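Package: fibermosaic
Title: Spatial Distribution and Fractal Organization of Muscle Fiber Type Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of two-dimensional point patterns of muscle
    fiber types. Builds radial-basis-function distribution functions on a
    square grid (per-cell Gaussian kernels with covariance regularization) and
    measures reproducing-kernel distance and angle between them, so fiber-type
    spatial distributions can be compared within and across muscle fascicles.
    Estimates fractal organization of binary fiber images with the correlation
    method, fitting the generalized power law N = a*eps^D + c by nonlinear
    least squares and classifying fractality from the pre-form factor. Includes
    generators for synthetic validation geometries (ball, ring, sum, cross)
    and the orchestration to reproduce the synthetic dissimilarity experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    nortest,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
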