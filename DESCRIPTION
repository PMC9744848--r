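Package: placegrid
Title: Coupled Place-Cell and Grid-Cell Simulation of Path Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the hippocampal-entorhinal navigation loop in a square
    arena: five twisted-torus continuous-attractor grid modules path-integrate
    a synthetic exploration trajectory, while a Hodgkin-Huxley-based place-cell
    population with proximity sensing and visual-blob feature matching forms
    place fields that dynamically correct the accumulated path-integration
    error.  Provides trajectory generators, the coupled simulation loop,
    gridness scoring from rate-map autocorrelograms, and an entropy/complexity
    suite for place-field distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
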