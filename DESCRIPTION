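Package: rootcortex
Title: Root Cortical Phenotypes and Nitrogen Capture In Silico
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Functional-structural simulation of maize root systems under
    suboptimal nitrogen, focused on root cortical phenotypes. Fits the
    anatomical cost model linking cortical cell file number and cortical
    cell size to root respiration, tissue nitrogen requirements and root
    diameter; generates synthetic parameterization datasets; runs a
    daily-step carbon source-sink root/soil simulator with per-segment
    nitrogen uptake, aerenchyma development and one-dimensional nitrate
    leaching; and orchestrates transphenic decompositions, sensitivity
    grids and phene-by-soil factorial experiments with replicate
    management.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
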