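Package: cox2screen
Title: Simulation and Scoring of a COX-2 Promoter-Reporter Chemotherapy Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-content live-imaging screens that track
    cyclooxygenase-2 (COX-2/Ptgs2) promoter activity with a destabilized GFP
    reporter alongside cell confluence. Provides a deterministic kinetic model
    of chemotherapy-induced Ptgs2/COX-2/PGE2 and reporter dynamics, a synthetic
    1280-compound plate-based screen generator (per-well time series and
    rendered two-channel fields with ground-truth manifests), Incucyte-style
    segmentation (top-hat GFP object detection, texture-based confluence),
    control-normalized GFP and confluency scoring with hit classification and
    autofluorescence QC, and an expression-pharmacodynamics stage for
    NCI-60-style panels (baseline bimodality split, GI50 quartiles,
    sensitivity-induction correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    withr,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
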