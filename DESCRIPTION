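Package: pcthresh
Title: Energy-Threshold Optimization for Photon-Counting Effective Atomic
    Number Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for two-bin photon-counting x-ray imaging:
    filtered tungsten-anode spectrum generation, Beer-Lambert transmission,
    per-channel Poisson counting noise, the three-step effective atomic
    number (Z) estimation algorithm (attenuation factor, beam-hardening
    correction, calibration-curve inversion), first-order Poisson error
    propagation to the Z estimate, and a 1 keV-resolution energy-threshold
    sweep over tube voltages that locates the minimum-uncertainty threshold
    per voltage. Results are returned as tibbles with broom-style tidiers
    and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
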