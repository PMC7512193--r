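Package: neqdecide
Title: Non-Equilibrium Thermodynamics of Bounded-Rational Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating bounded-rational decision-makers in changing
    utility landscapes and verifying the non-equilibrium relations that govern
    them. Provides Boltzmann equilibrium policies from a free-energy trade-off
    between expected utility and a Kullback-Leibler information cost, rejection
    sampling and Metropolis-Hastings decision mechanisms with anytime (finite
    sample budget) behaviour, trajectory-level thermodynamic accounting (utility
    gain, deliberation cost, dissipation, forward and backward path
    probabilities), Crooks fluctuation-theorem and Jarzynski-equality checks
    with exhaustive-enumeration oracles, one-step-lag adaptation and quasi-static
    limits, Bayesian inference as free-energy maximisation with batch-size
    dependent surprise and dissipation, and Langevin (Ornstein-Uhlenbeck)
    deliberation dynamics with closed-form Fokker-Planck solutions. Includes
    config-driven experiment runners with tabular (tibble/CSV) outputs and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve,
    withr
Config/testthat/edition: 3
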