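Package: midpiece
Title: Quantitative Analysis of Sperm Midpiece Contraction and Actin Helix Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse fluorescence imaging of the mouse
    sperm flagellar midpiece during acrosomal exocytosis and gamete fusion.
    Builds longitudinal and cross-section kymographs, estimates midpiece
    diameter by profile autocorrelation, detects contraction onsets and
    initiation foci, tracks membrane and actin fluorescence peaks with velocity
    fits, relates membrane-dye fluorescence to normalized diameter through a
    linear model, estimates actin double-helix geometry (radial distribution,
    pitch frequency, gyre count) from single-molecule localization tables,
    computes Manders colocalization coefficients and number-and-brightness
    maps with detector correction, and classifies calcium and membrane-dye
    event ordering in ROI traces. A synthetic-data generator emulates every
    input with known ground truth so all stages are testable without raw
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    withr,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
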