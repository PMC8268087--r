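Package: ivdmech
Title: Viscoelastic Indentation and Collagen Orientation Analysis for
    Developing Intervertebral Disc Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for quantifying the micromechanics and microstructure of
    soft embryonic spine tissue. Implements ramp-hold spherical
    nanoindentation analysis with a standard-linear-solid relaxation
    function under elastic-viscoelastic correspondence (a Boltzmann
    hereditary integral over Hertzian contact), including contact-point
    detection, bounded nonlinear least-squares fitting, derived
    instantaneous/equilibrium moduli and elastic fraction, and
    measurement-validity checks. Quantifies collagen fibre orientation in
    grayscale images via cubic-spline-gradient structure tensors with
    Gaussian windowing, intensity/coherency masking, four-quadrant region
    statistics and axial circular summaries. Provides nested
    group-versus-group comparisons (group fixed, specimen random) with
    three-standard-deviation outlier exclusion, plus seeded synthetic-data
    generators (trapezoidal indentation curves, hierarchical cohorts,
    fibrous phantom images) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    lmerTest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
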