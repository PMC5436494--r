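Package: flowramp
Title: Transient Flow-Ramp Kinetics for Automated Flow Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for generating multistep kinetic models from transient
    flow-ramp experiments in tubular flow reactors. Implements the linear
    flow-ramp residence-time transform (with thermal-expansion correction),
    a virtual flow-rig simulator for SNAr-type reaction networks with
    Arrhenius temperature dependence, global nonlinear least-squares fitting
    of rate constants and activation energies across all profiles
    simultaneously, rate-order model discrimination, and Taylor-Aris /
    closed-vessel dispersion theory for coiled reactors including
    F-curve estimation of the coil dispersion ratio and the resulting
    bias in fitted rate constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
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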