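Package: tracheamech
Title: Mechanical Characterization and Hyperelastic Modelling of Tracheal Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processes uniaxial tensile tests of tracheal cartilage, smooth
    muscle and inter-ring connective tissue from raw force-displacement
    records to Cauchy stress-stretch curves, fits seven isotropic
    incompressible hyperelastic strain-energy functions (Neo-Hookean,
    Mooney-Rivlin, Yeoh, Fung, Humphrey, Ogden, Veronda-Westmann) by
    multistart Levenberg-Marquardt least squares, ranks models by the
    coefficient of determination, extracts the linear Young's modulus of
    cartilage, and compares tissue stiffness between age groups and sexes
    by two-way analysis of variance.  A calibrated synthetic-cohort
    generator emulates the statistical structure of a donor cohort so that
    every pipeline stage is testable without access to cadaver data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
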