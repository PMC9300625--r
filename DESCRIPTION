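Package: vascmet
Title: Hybrid 3D Multiscale Simulation of Vascular Tumour Growth with
    Cell-Level Central Carbon Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates vascular tumour growth on a 3D lattice by coupling a
    stochastic cellular automaton of normal and cancer cells, quasi-steady
    reaction-diffusion fields for oxygen, VEGF and glucose, a stochastic
    angiogenesis model with a distance-dependent anastomosis probability,
    Poiseuille blood flow with shear-driven radius remodelling on the vessel
    network, and a per-cell lin-log kinetic model of central carbon
    metabolism. Produces spatially resolved extracellular and intracellular
    metabolite fields over the course of tumour growth, with deterministic
    seeded runs, plain-text snapshots and checkpoint/restart.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
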