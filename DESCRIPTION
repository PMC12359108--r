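Package: dpimd
Title: Dissociative Photoionization Molecular Dynamics on Reactive Toy Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dissociative photoionization of
    small molecules by Born-Oppenheimer molecular dynamics. Provides thermal (NVT)
    sampling of the neutral molecule, vertical-ionization energy bookkeeping,
    randomized deposition of the photon excess energy into nuclear kinetic energy,
    constant-energy fragmentation trajectories with an energy-conservation filter,
    fragment detection by distance-graph connectivity, charge assignment by
    Stevenson's rule, energy-resolved mass spectra, breakdown diagrams,
    first-occurrence trees, and reaction-mechanism event tracing. The
    electronic-structure engine is abstracted behind a potential-energy-surface
    contract; a bundled reactive Morse-plus-angle toy potential for a 12-atom
    thiouracil-like ring allows every stage to run without external software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
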