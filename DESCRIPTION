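Package: tumimm
Title: Size- and Space-Structured Simulation of Tumor-Immune Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulator for the interaction between a
    size-structured tumor cell population and space-structured immune
    responses. Couples a growth-fragmentation equation for tumor cells
    (Gompertz or constant growth, binary division) to chemotactic
    convection-diffusion equations for antitumor and protumor immune
    cells on the unit disc, with a cytokine relay that activates the
    protumor arm above a critical tumor mass. Provides the leading
    eigenpair of the growth-fragmentation operator by the power method,
    a reduced five-state ODE model with closed-form equilibria and
    stability classification, a stationary-system predictor for the
    equilibrium tumor mass, and pulsed immunotherapy extensions
    (reactivation of exhausted effector cells, cytokine blockade, and
    their combination). Simulations classify outcomes as equilibrium or
    escape and write reproducible time series and manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
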