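Package: foliometry
Title: Non-Destructive Leaf Size and Shape Analysis from Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contour-based leaf morphometry and allometric modelling for
    plant breeding populations. Computes leaf length, maximum perpendicular
    width and blade area from digitized leaf outlines, fits the Montgomery
    proportionality model (LS = alpha * L * W) and the power-law similarity
    model (LS = alpha * L^beta) by least squares, builds percentile-bootstrap
    confidence intervals for the allometric parameters and evaluates
    reference-value hypotheses, derives the ellipticity index (4 * alpha / pi),
    and groups progenies in (leaf size, width-to-length ratio, ellipticity)
    space with partitioning-around-medoids clustering plus the accompanying
    multivariate test battery. Includes a synthetic-leaf generator with
    analytically known shape parameters for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
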