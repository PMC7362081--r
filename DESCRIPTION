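Package: mfrelease
Title: Multifractal Hydrodynamic Modelling of Controlled-Release Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models cumulative fertilizer or drug release from polymer matrices
    with a multifractal hydrodynamic model: closed-form density and velocity
    fields of a spreading structural-unit distribution, a scale-fractality
    relation linking the diffusion-like coefficient to an effective fractal
    dimension, and a mass-release law obtained as the local density depletion.
    Provides stage-wise nonlinear calibration of the release law on three-stage
    dissolution profiles, linearized fits of the five classical release-kinetics
    models (zero order, first order, Higuchi, Korsmeyer-Peppas, Hixson-Crowell),
    a mass-balance correction for withdrawal/replacement sampling protocols, and
    a synthetic release-experiment generator emulating an in vitro urea release
    protocol so that every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
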