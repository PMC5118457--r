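Package: photokin
Title: Parameterization of C3 and C4 Photosynthesis Models with
    Species-Specific Enzyme Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for fitting biochemical models of leaf photosynthesis
    to combined gas-exchange and chlorophyll fluorescence measurements.
    Implements the variable-J estimation of mesophyll conductance, the
    Farquhar-von Caemmerer-Berry (FvCB) model of C3 photosynthesis fitted
    on a chloroplastic CO2 basis, and the enzyme-limited von Caemmerer
    model of C4 photosynthesis, together with Michaelis-Menten kinetic
    constants of Rubisco and PEPC for rice, wheat and maize at 25 and
    38 degrees C and their temperature scaling.  Includes temperature
    sensitivity and acclimation indices, a paired-refit analysis that
    quantifies the bias introduced by parameterizing the models with
    standard tobacco kinetics instead of species-specific constants, and
    a synthetic gas-exchange generator for validating the whole pipeline
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
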