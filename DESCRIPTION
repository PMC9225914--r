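Package: moxitherm
Title: Bioheat Simulation of Mild Moxibustion and Orthogonal Parameter Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transient Pennes bioheat simulation of mild moxibustion: a
    three-layer skin/fat/muscle block is heated through surface-to-surface
    radiation from the glowing end of a moxa stick whose temperature follows a
    harmonic burning law with periodic ash-cleaning. Provides an axisymmetric
    finite-volume solver with radiative surface boundary conditions, scenario
    configuration, univariate parameter sweeps, calibration and validation
    against a published in-vivo temperature series, and Taguchi L9(3^4)
    orthogonal-design machinery (range analysis and saturated-design ANOVA)
    for ranking the factors that control thermal penetration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
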