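Package: flexmarine
Title: Configurable Marine Modelling on Orthogonal Unstructured Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale framework for coupled marine modelling on 2D
    orthogonal unstructured meshes with z-layer vertical discretization.
    Provides a hydrostatic semi-implicit free-surface hydrodynamic solver
    on the C-grid, finite-volume advection-diffusion of pelagic tracers,
    a text-configurable equation solver for user-defined pelagic, benthic
    and sediment models (including settling, resuspension and
    pelagic-benthic exchange), a surface heat-budget model, a Lagrangian
    agent-based module with connectivity analysis, and offline
    hydrodynamic forcing.  Models from 0D box configurations to full 3D
    setups are composed from XML setup files without programming.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
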