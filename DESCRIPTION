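Package: cardiomech
Title: Multiscale Cardiac Electromechanics Under Varying Myocardial
    Conduction Velocity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale multiscale simulation of ventricular
    electromechanics. A human ventricular ionic model with transmural
    (endocardial, mid-myocardial, epicardial) variants is propagated
    through monodomain tissue on fixture geometries, cellular resistivity
    is calibrated to target myocardial conduction velocities, and the
    resulting electrical activation maps drive a cross-bridge myofilament
    model one-way coupled to a lumped ventricle surrogate and a
    two-compartment-per-circulation Windkessel loop. The package
    quantifies how conduction velocity alters activation time,
    pressure-volume behaviour, contractile ATP consumption, and pumping
    efficiency (stroke work per ATP), and ships the synthetic fixture
    generators, sweep orchestration, and trend analysis used to do so.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
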