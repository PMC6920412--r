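Package: thylakoidSAS
Title: Small-Angle Scattering Models for Stacked Double-Bilayer Thylakoid
    Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic small-angle neutron and X-ray scattering model for
    stacked double-bilayer (thylakoid-type) membrane systems: a box-profile
    double-bilayer form factor, a finite-stack Caille structure factor,
    Gaussian polydispersity over lumen width and repeat distance, per-point
    Gaussian instrument-resolution smearing and a flat-plus-power-law
    background. Includes a brute-force Debye-equation point-cloud simulator
    for model validation, a staged constrained chi-square fitting engine with
    profile-likelihood intervals, a scattering-length-density scenario solver
    that estimates lumenal protein content from paired neutron/X-ray
    contrasts, and a synthetic-curve generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
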