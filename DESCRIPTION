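Package: agederm
Title: Age-Dependent Electromagnetic and Thermal Dosimetry of Near-Surface Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analytical dosimetry of human skin exposed to 26 and 60 GHz plane
    waves as a function of age. Implements a stratified-media plane-wave solver
    (transmission coefficient, absorbed power density, SAR depth profiles,
    per-layer power budget), a steady-state multilayer Pennes bioheat solver
    with convective surface and perfused-tissue boundary conditions, a
    Lichtenecker hydration model mapping total body water to tissue
    permittivity, age sweeps over exposure scenarios, ICNIRP local exposure
    limits, and Monte Carlo propagation of inter-individual variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
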