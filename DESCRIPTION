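Package: mcdtsim
Title: Simulation of Magnetically Controlled Intraperitoneal Drug Targeting in Solid Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic multiphysics simulator of intraperitoneal (IP)
    chemotherapy of a peritoneal tumor, with and without magnetic-nanoparticle
    drug targeting. Solves steady Darcy interstitial fluid flow with Starling
    transvascular exchange on a circular tumor, evaluates the analytic
    magnetostatic field of a rectangular permanent magnet and the resulting
    saturable force and Stokes drift on drug-coated magnetic nanoparticles,
    integrates the coupled free/bound/internalized drug concentration fields
    (convection-diffusion-reaction with receptor binding, internalization and
    pore-model transvascular loss) by an implicit finite-volume scheme on a
    graded polar grid, and reports treatment-efficacy metrics: penetration
    half-depth, relative penetration area, and fractions of killed cells from
    an exponential cell-survival model. Includes scenario sweeps over particle
    size, magnet remanence and magnet distance, two scalar calibration
    routines, and independent analytic/quadrature oracles for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
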