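Package: antforage
Title: Closed-Loop Excitable-System Model of Harvester Ant Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of collective foraging regulation in
    desert harvester ant colonies modelled as a closed-loop excitable system.
    Incoming foragers drive a leaky-integrator stimulus, available foragers
    respond through FitzHugh-Nagumo excitability whose suprathreshold
    oscillations are outgoing foragers, and foraging trips outside the nest
    are random delays drawn from a chi-square distribution, closing the loop.
    Provides event-sequence utilities (sliding-window rate estimation,
    Poisson fixtures), exact propagation of the shot-noise stimulus and its
    stationary density, FN bifurcation structure and limit-cycle period
    approximations, infinite-server queueing results for the foraging delay,
    a two-population (informed/uninformed volatility) closed-loop colony
    simulator, and analytic nest input/output curves with iterated-map
    fixed-point analysis of the quasi steady-state foraging rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    stats,
    tibble,
    dplyr,
    generics,
    ggplot2,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
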