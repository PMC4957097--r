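Package: turgorkit
Title: Osmotic Potential Estimation, Osmolyte Association and Turgor
    Actuator Simulation for Model Plant Cytosols
Version: 0.1.0
Authors@R:
    person("turgorkit", "developers", email = "turgorkit@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative study of osmolyte cooperation in
    model plant cytosols (KCl, D-glucose, L-glutamine). Implements a
    non-ideal Van 't Hoff estimator of osmotic potential, the osmotic
    potential ratio and osmolyte association degree statistics, a
    mass-action model of the four-member K+.Cl-.D-Glc.L-Gln supramolecular
    complex with speciation and dilution curves, and an ODE simulator of a
    plant-cell-inspired osmotic actuator in free-piston (constant
    pressure) and bulging-disk (turgor) modes with per-solute membrane
    rejection and leak. Includes synthetic instrument-data generators
    (cryo-osmometry replicates, quantized pressure traces, piston
    displacement traces) and parameter-recovery harnesses, plus a small
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    digest,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
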