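Package: caspike
Title: Multiscale Stochastic Simulation of Intracellular Calcium Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid deterministic-stochastic simulator for intracellular
    calcium spiking driven by single-channel noise. IP3 receptor channels are
    simulated as DeYoung-Keizer Markov chains, channel clusters act as point
    sources with quasi-static currents, and the linearized three-species
    (free calcium, mobile buffer, immobile buffer) cytosolic field in a
    spherical cell is solved analytically by a Green's-function eigenmode
    expansion coupled to a well-mixed endoplasmic reticulum. Includes
    interspike-interval statistics (sigma versus mean relation, population
    slopes) used to characterise the simulated spike trains, a surrogate
    spike-train generator, plain-text configuration and experiment presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
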