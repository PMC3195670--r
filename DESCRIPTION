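Package: helixpack
Title: Crossing-Angle and Packing-Mode Analysis of Transmembrane Helix
    Dimer Ensembles
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of conformational ensembles of transmembrane (TM)
    helix dimers, of the kind produced by coarse-grained self-assembly or
    atomistic molecular dynamics simulations and by NMR ensemble
    deposition.  Fits helix axes, computes signed crossing angles with a
    right-handed/left-handed packing convention, builds 2D spatial
    probability-density maps of one helix around the other in the bilayer
    plane with watershed packing-mode detection, classifies per-simulation
    conformational stability from C-alpha RMSD time series, characterises
    helix/helix interfaces (contacts, GxxxG-face orientation, interface
    overlap), and provides a fully parameterised synthetic helix-dimer
    generator so that every analysis is testable as parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
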