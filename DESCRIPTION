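Package: quasitherm
Title: Thermodynamics of Templated Replication and Quasispecies Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the nonequilibrium thermodynamics of templated
    nucleic-acid replication and the population genetics it drives. From a
    4x4 table of base-incorporation rate constants and a chemical driving
    force, the package computes single-molecule elongation velocity and
    error rate (exact mean-field theory and kinetic Monte Carlo),
    population-level mean fitness and error thresholds on the single-peak
    Eigen landscape, gas/liquid/crystalline-analogue phase diagrams in the
    (inverse fidelity, thermodynamic force) plane, stochastic quasispecies
    and genome-crystallization dynamics, and closed-system starvation
    processes with their fidelity thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    seqinr,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
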