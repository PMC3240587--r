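Package: prc1dyn
Title: Kinetic Modelling of the Ring1B/Bmi1 Histone H2A Ubiquitination Switch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary-differential-equation models of the Ring1B/Bmi1
    ubiquitination cycle that controls histone H2A monoubiquitination by
    Polycomb repressive complex 1. Implements the Michaelis-Menten and
    mass-action formulations of the 13-reaction scheme with intermolecular
    autocatalytic self-ubiquitination, enumerates steady states with
    stability analysis, scans saddle-node bifurcations and hysteresis
    protocols, detects relaxation oscillations and excitable all-or-none
    responses, and maps dynamical regimes over Bmi1 and USP7 abundance.
    Includes a synthetic-data module (noisy pseudo-observed time courses,
    randomized parameter sets, parameter recovery) and SBML Level 3 export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
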