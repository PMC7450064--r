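Package: fmnptrack
Title: Single-Particle Tracking and Femtonewton Force Calibration for
    Magnetic Nanoparticle Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse single-particle tracking (SPT)
    experiments in which fluorescent magnetic nanoparticles bound to
    membrane molecules are pulled laterally by a magnetized needle.
    Provides a drift-diffusion trajectory simulator with a configurable
    needle force field and synthetic camera rendering, sub-pixel spot
    localization and nearest-neighbour linking, mean-squared-displacement
    diffusion estimation with the standard mobility filters, femtonewton
    force estimation from the drift-to-diffusion ratio F = kB*T*v/D,
    log-normal diffusion statistics, and fiducial-based nonreflective
    similarity registration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
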