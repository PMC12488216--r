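Package: ewaldhand
Title: Handedness Determination and Validation of CryoEM Reconstructions
    by Ewald-Sphere Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates phase-corrected single-particle cryoEM images into
    their Hermite (real) and anti-Hermite (imaginary) Fourier components and
    performs independent gather-based 3D reconstructions from each, following
    the curved Ewald sphere and its Friedel mate. The sign of the Fourier
    shell correlation between the imaginary-component map and the
    R^2-modulated real-component map (the I-R FSC) determines the absolute
    hand of the reconstruction, and its agreement with a predicted curve
    validates reconstruction correctness. Includes a synthetic-data module
    (chiral phantoms, curved-sphere projections with CTF phase and noise),
    MRC2014 and STAR readers/writers, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
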