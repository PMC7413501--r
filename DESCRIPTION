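Package: plateKinetics
Title: Growth Kinetics from Microtiter-Plate Optical Density Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of maximum specific growth rates, lag-phase durations
    and maximum optical densities of filamentous fungi (or other microbes)
    cultivated in microtiter plates, from noisy plate-reader OD time courses.
    Per-well estimates are obtained from penalized cubic smoothing splines
    fitted to log-transformed OD, with a user-set smoothing factor on a 0-1
    scale, rolling-median despiking of pellet-induced spikes, and
    tangent-method lag times. Replicate statistics reproduce the usual
    strain-by-substrate summary tables: mean +/- SEM, one-way ANOVA, protected
    Fisher LSD compact letter displays, and Student t comparisons between
    cultivation systems. A seeded synthetic-plate generator with
    Zwietering-Gompertz ground truth and instrument artifacts (spikes,
    edge-well evaporation, lid condensation, data-collection gaps) supports
    parameter-recovery validation, together with an inoculum carryover
    calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
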