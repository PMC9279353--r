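Package: guvflux
Title: Single-Vesicle Proton Permeation Analysis for GUV Acid-Addition Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies passive proton permeation across single giant
    unilamellar vesicles (GUVs) from two-channel confocal time-lapse
    recordings of pyranine-loaded vesicles. Provides a forward simulator of
    GUV acidification under strong- or weak-acid addition (Goldman-Hodgkin-
    Katz electrodiffusion with capacitive membrane-potential buildup and
    Henderson-Hasselbalch weak-acid speciation), a synthetic two-channel
    image renderer, Hough-circle vesicle detection and nearest-neighbour
    tracking, intensity-to-pH calibration with analytic buffer capacity,
    per-vesicle flux profiling and linear-regime permeability fitting, GHK
    inversion for transmembrane potential, proton motive force computation,
    and ionic/neutral weak-acid flux decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tools,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
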