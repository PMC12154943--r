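Package: covkin
Title: Mass-Action Kinetics of Covalent Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulation and analysis of covalent-inhibition
    kinetics. Arbitrary Markovian mass-action schemes are defined as
    stoichiometry matrices and integrated with a stiff ODE solver (LSODA);
    built-in schemes expand the noncovalent intermediate into reactive and
    nonreactive conformations and reduce it under the rapid-equilibrium
    approximation. The analysis layer covers drug-target residence time,
    the kobs/KIapp dose-rate workflow for irreversible inhibitors
    (kinact/KI), an analytic time-dependent EC50 for covalent occupancy
    dose-response curves, Hill-equation fitting, and global fitting of
    parameterized simulations to dose-time covalent-occupancy surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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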