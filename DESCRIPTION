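Package: wristpet
Title: Desk-Scale Simulation of a Wrist-Worn PET Coincidence Detector for
    Blood Time-Activity Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for an in-silico feasibility study of a non-invasive,
    wrist-worn coincidence detection unit that measures the arterial blood
    time-activity curve (BTAC) during PET studies.  The package generates
    arterial and venous input-function curves from a piecewise
    linear-exponential model, advects them through the radial and ulnar
    vessels of a cylindrical forearm phantom with uniform or pulsatile
    plug flow, transports annihilation photons through the phantom with
    Beer-Lambert attenuation and single Klein-Nishina Compton scatter,
    detects them on rings of monolithic scintillator blocks with energy
    blurring, energy windowing and non-paralyzable deadtime, sorts and
    classifies coincidences, and summarises the result as count-rate
    curves, noise-equivalent count rates (NECR), sensitivities and
    detector-configuration gain tables.
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
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
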