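Package: afplatform
Title: Simulation and Analysis for Aerodynamic Force Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A virtual aerodynamic force platform (AFP): an instrumented box whose
    walls mechanically integrate the wall pressure so the net unsteady aerodynamic
    force of an object flying inside is read from the ground reaction forces.
    Provides the control-volume theory (screening numbers, a spectral Neumann-Poisson
    wall-pressure solver for an interior point force, wall-integral force recovery,
    aperture sensitivity, Blasius shear bounds, and a compressible phase-delay
    demonstration), a load-cell instrument simulator (modal structural dynamics,
    quantization, calibration), the measurement analysis pipeline (Butterworth
    filtering, validation metrics, natural-frequency estimation, wingbeat-resolved
    weight support), and seeded generators for quadcopter-like thrust profiles and
    bird-like flapping-flight forces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
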