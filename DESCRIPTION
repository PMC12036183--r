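Package: microext
Title: Desk-Scale Micro-Extensometer Simulation, Control, and Tensile Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual micro-extensometer for uniaxial tensile testing of
    small biological specimens. Simulates a viscoelastic-plastic specimen
    (standard linear solid with a Lockhart-style yield-threshold creep
    element and threshold grip slip), a stepper-screw actuator, a noisy
    Wheatstone-bridge load cell, and a synthetic camera; re-implements the
    load-cell offset/gain calibration workflow, automated ramp and
    constant-force creep experiments with synchronized logging and
    snapshots, sub-pixel landmark tracking for optical strain measurement,
    and stress-strain analysis (Young's modulus, ultimate stress, yield
    onset, windowed creep rates, grip-slippage diagnosis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
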