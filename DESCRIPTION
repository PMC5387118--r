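Package: cellspray
Title: Cell Viability Prediction for Droplet-Based Cell Deposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical prediction of single-cell survival after impact of a
    cell-containing droplet, as occurs in cell spraying, inkjet bioprinting and
    laser-assisted cell transfer. The model chains Weber-number spreading laws,
    compound-droplet cushioning, oblate-spheroid membrane-area expansion and a
    critical-stretch survival law into a per-droplet survival probability, and
    averages it over polydisperse spray spectra. Includes a seeded synthetic
    spray-spectrum generator, a double-pulse shadowgraph image simulator with
    droplet detection and velocimetry, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
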