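Package: phikinet
Title: Phi-Order Photokinetics Under Monochromatic Light
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of photoreaction kinetics driven by
    monochromatic light. Integrates the nonlinear photokinetic rate law for
    arbitrary unimolecular photomechanisms with fixed-step fourth-order
    Runge-Kutta, fits concentration and total-absorbance traces with the
    unifying Phi-order model, recovers absorption coefficients and per-step
    quantum yields from traces, and determines the incident photon flux by
    chemical actinometry and kinactinometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
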