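Package: npwrap
Title: Receptor-Mediated Nanoparticle Wrapping and Internalization Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuum simulation of receptor-mediated nanoparticle
    internalization into endothelial cells. Couples an axisymmetric
    inextensible bending membrane to a Kelvin-Voigt viscoelastic cytoplasm
    and to ligand-receptor bond kinetics with a force-dependent (Bell)
    dissociation rate, and advances the coupled system in time to an
    equilibrium wrapping state. Includes closed-form scaling estimates for
    firm-adhesion onset, wrapping kinetics and depth scalings, and scripted
    parameter-sweep experiments (particle radius, bond properties, cell
    mechanical properties, applied vertical force).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
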