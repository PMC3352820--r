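Package: microcosm
Title: Eco-Evolutionary Analysis of Bacterial Microcosm Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for experimental evolution of bacterial
    communities in serial-transfer microcosms: optical-density growth assays
    with colony-count calibration and maximum growth rate (V_MAX) estimation,
    spent-medium assays turned into signed species-interaction networks, NMR
    metabolic-footprint statistics with Monte Carlo permutation tests on
    multivariate Euclidean distances, cross-feeding delta-statistics linking
    evolved production to evolved consumption, serial-transfer demography
    (generations and effective population sizes), and colorimetric (MicroResp)
    community respiration rates. A parameterised synthetic-community generator
    emulates every assay so each stage can be tested against known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
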