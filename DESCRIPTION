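Package: sbecontrol
Title: Transmission Modelling, Optimal Control and Cost-Effectiveness of
    Snakebite Envenoming Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A compartmental human-snake model of snakebite envenoming (SBE)
    with public-health-awareness and antivenom-treatment interventions.
    Provides deterministic simulation of the coupled ordinary-differential
    system, calibration of parameters and initial conditions to monthly
    cumulative surveillance series by bounded least squares and adaptive
    random-walk Metropolis MCMC with Gelman-Rubin convergence diagnostics,
    a two-control optimal-control solver based on the fourth-order
    Runge-Kutta forward-backward sweep, and a cost-effectiveness layer
    computing discounted intervention costs, incremental cost-effectiveness
    ratios with dominance elimination, DALY conversion and GDP-per-capita
    threshold classification. A synthetic registry-data generator emulates
    hospital surveillance tables so the whole pipeline is testable without
    access to restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
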