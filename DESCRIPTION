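Package: fogait
Title: Hybrid Neuromechanical Models of Freezing of Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Parkinsonian walking and freezing of gait with a pair of
    hybrid dynamical models of the stance phase: a forced planar biped and a
    reduced forced inverted pendulum, both with impulsive heel-strike resets.
    Plantar-flexor muscle activity enters as sinusoidal ankle push-off and
    stance-leg torques. Provides event-located hybrid integration with
    freeze detection, the analytic stance-phase flow of the linearised
    pendulum, the one-dimensional stride return map with fixed points,
    periodic orbits and stability multipliers, bifurcation diagrams with
    period-doubling (Feigenbaum) accumulation estimation, walk-time heatmaps,
    and shooting solutions of the stance boundary-value problem. Results are
    returned as tibbles with tidy(), glance() and autoplot() methods.
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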