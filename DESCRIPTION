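Package: hexagait
Title: Hexapod Wave Gaits from Decoupled Oscillators with Foot-Contact
    Phase Resetting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@hexagait.org",
           role = c("aut", "cre"))
Description: Models interlimb coordination in slow hexapod walking as six
    decoupled phase oscillators, one per leg, coupled to the body only
    through foot-contact sensory feedback (phase resetting) and a
    contralateral antiphase constraint.  Provides the oscillator network
    controller with its foot trajectory map, a quasi-static spring-leg
    body model solved by force and moment balance, an event-driven
    simulator of the reduced phase dynamics with Poincare-map analysis
    (fixed points, linear stability, basins of attraction, footprint
    diagrams), and the closed-form fixed points and stability multipliers
    of the direct and retrograde wave gaits as analytic cross-checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
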