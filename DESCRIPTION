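Package: guvmotility
Title: Motility Analysis of Active Micromotors Confined in Giant Unilamellar Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Brownian-dynamics simulation and single-particle-tracking analysis of
    enzyme-powered coacervate micromotors confined in giant unilamellar vesicles
    (GUVs). Provides an active-Brownian-particle simulator with a hydrodynamic
    wall-drag (position-dependent mobility) model and fuel-dependent propulsion,
    synthetic microscopy rendering (bright-field-like frames and confocal-like
    z-stacks), particle detection and nearest-neighbour linking, time-averaged
    mean-square-displacement (MSD) computation, anomalous-exponent and
    diffusion-coefficient fitting, diffusion-regime classification, and an
    experiment orchestrator for bulk-versus-confined, fuel-sweep,
    compartment-size and particle-crowding studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
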