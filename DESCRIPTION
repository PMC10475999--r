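Package: vpdresponse
Title: Segmented Transpiration Response Phenotyping Under Rising Vapour
    Pressure Deficit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for step-change vapour pressure deficit (VPD)
    phenotyping experiments on well-watered plants. Converts leaf gas-exchange
    time series and gravimetric balance logs into per-level steady-state
    tables, derives transpiration reduction, photosynthetic limitation,
    stomatal reduction and intrinsic water use efficiency, fits segmented
    (broken-stick) regressions of transpiration rate on VPD with per-plant
    intercepts and a Davies significance test for the breakpoint, and clusters
    accessions into phenotypic groups by k-means over a scaled trait matrix
    projected onto principal components. Ships a synthetic-cohort generator
    with a ground-truth manifest so every pipeline stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
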