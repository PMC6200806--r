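Package: phasemammo
Title: Simulation, Dosimetry and Image-Quality Analysis for Grating-Based
    Phase-Contrast Mammography at a Compact Synchrotron Source
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and analysis chain for monochromatic
    mammography at an inverse-Compton compact synchrotron source.
    Models the quasi-monochromatic source spectrum and beam footprint,
    synthesises digital accreditation and breast-texture phantoms,
    simulates two-grating Talbot interferometer phase-stepping
    acquisitions with Poisson noise, retrieves transmission,
    differential-phase and dark-field images, computes air kerma and
    mean glandular dose from normalized glandular dose coefficients,
    and provides contrast-to-noise-ratio, power-spectrum resolution and
    accreditation-phantom scoring analyses, plus tile stitching with
    linear-ramp blending and an end-to-end dose-study driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
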