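Package: dsipmopt
Title: Architecture-Level Sensitivity Optimization for Digital Silicon
    Photomultipliers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analytic models and Monte-Carlo simulators for the design of
    digital silicon photomultiplier (dSiPM) pixels used in PET detectors.
    Provides Poisson models of spatial (microcell) and temporal (OR-bus)
    pile-up, fill-factor and SPAD-count bookkeeping under a per-block area
    budget, a dark-count-rate (DCR) resampling estimator of SPAD yield
    versus active area, a design-space optimizer over SPADs-per-microcell,
    subpixels-per-pixel and SPAD active area, the closed-form saturating
    photon-counting response, a discrete-event subpixel simulator that acts
    as an independent oracle for the analytic formulas, and a simplified
    scintillation-spread simulator for first-photon pixel-multiplicity
    studies in monolithic-crystal PET detector blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
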