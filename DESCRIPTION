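Package: rodcone
Title: Simulation and Analysis of Rod-Cone Gap-Junction Coupling in
    Photoreceptor Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying electrical coupling between rod and cone
    photoreceptors through gap junctions. Implements a predicted cone
    flash-response spectral model based on S/M-opsin coexpression
    gradients, a two-node equivalent circuit of a cone coupled to its rod
    pool with steady-state solutions and response-polarity classification,
    builders for kinetics, spectral and background light-stimulation
    protocols, a seeded generator of synthetic photovoltage recordings
    (coupling growth, rundown, gap-junction blocker pharmacodynamics,
    baseline noise), and a measurement pipeline for flash responses
    (box-car filtering, peak amplitude and time-to-peak, spectral ratios,
    hyperbolic intensity-response fits, recovery curves, rank-sum tests,
    and time-zero coupling extrapolation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
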