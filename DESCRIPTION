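Package: darkscatter
Title: Dark-Field X-Ray Imaging by Varying Collimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulation of X-ray photon transport (photoelectric
    absorption, Rayleigh and Compton scattering) through box phantoms, scored
    behind anti-scatter collimators of different aspect ratios. Digital
    subtraction of projections taken with high and low collimation, or at two
    object-detector distances, extracts the small-angle-scattering
    (dark-field) image. Includes the analytic single-scattering forward model
    with collimator angular-acceptance limits, Klein-Nishina Compton sampling,
    a calibrated analytic Rayleigh form factor, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
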