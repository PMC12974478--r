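Package: dualscale
Title: Dual-Timescale Homeostatic Regulation in a Bursting Neuron Model
Version: 0.1.0
Authors@R: person("dualscale", "maintainers", email = "dev@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a single-compartment conductance-based
    bursting neuron whose intrinsic parameters are governed by activity-dependent
    homeostatic feedback acting on two timescales: slow regulation of maximal
    conductances (channel densities) and fast shifting of activation and
    inactivation half-voltages (posttranslational modification). Includes a
    compiled integrator, calcium-sensor error signals, repeated high-potassium
    perturbation protocols, seeded ensemble generation, burst-onset latency
    metrics, parameter-space trajectory geometry (displacement norms, bounding
    spheres, tail-to-tail angles), and nonparametric group statistics
    (Kruskal-Wallis with Dunn's post hoc test and Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
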