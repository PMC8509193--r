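Package: dicentra
Title: Monte Carlo Simulation of Lymphocyte Dicentrics and Mixed-Field RBE
    for Therapeutic Ion Beams
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates radiation-induced dicentric chromosome aberrations in
    human peripheral blood lymphocytes with a Monte Carlo model of critical
    lesion induction and distance-dependent fragment mis-rejoining, calibrates
    the lesion-yield parameter against dicentric dose-response curves, builds a
    radiobiological database of linear-quadratic coefficients as a function of
    ion species and linear energy transfer (LET), and evaluates per-voxel
    relative biological effectiveness (RBE) and RBE-weighted dose for mixed
    particle fields along therapeutic carbon-ion beams.  A synthetic
    spread-out-Bragg-peak scoring generator and a pseudo-experiment generator
    stand in for transport-code output and literature dose-response data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
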