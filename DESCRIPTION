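Package: admittr
Title: Admittance-Based Mixed-Electrolyte Concentration Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation toolkit for admittance-based
    electrolyte sensing with coplanar insulated electrodes. Models the
    electrode/sample lumped equivalent circuit, the phase-shift network and
    comparator-based differential amplifier in phasor form, and coherent
    in-phase/quadrature (I/Q) detection of the amplified response. Fits
    quadratic and linear response surfaces that map mixed NaCl/KCl
    concentrations to normalized I/Q responses at two working frequencies,
    and inverts them for the two concentrations by a closed-form linear
    initialization followed by Gauss-Newton refinement. Includes a synthetic
    measurement generator for end-to-end validation and a command-line
    interface for simulate/fit/estimate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
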