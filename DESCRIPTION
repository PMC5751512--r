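Package: fluxcal
Title: Localized Human-Body Heat-Flux Calorimetry with a Thermopile Minisensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a skin-contact heat-conduction calorimetric minisensor as a
    two-input/two-output linear time-invariant system, calibrates its
    sensitivities and time constants from thermostat-programmed runs
    (steady-state least squares plus Nelder-Mead pole/zero fitting), recovers
    the body-surface heat flux as a sum of exponentials by inverse fitting of
    the calorimetric signal, and derives thermal resistance and an
    order-of-magnitude tissue conductivity from the steady-state flux versus
    thermostat-temperature relation. A synthetic-signal generator with a PID
    thermostat emulation lets the whole chain be exercised and validated
    without an instrument.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
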