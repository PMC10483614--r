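Package: cdmquant
Title: Quantification of Collective Directional Migration in 3D Cluster
    Aggregation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify collective directional migration (CDM) of
    multicellular clusters embedded in 3D hydrogels from time-lapse
    microscopy, together with an agent-based assay simulator that provides
    ground truth. Includes extended-depth-of-field projection of z-stacks by
    local-variance maximisation, bulk/protrusion segmentation, small-object
    filtering and object counting; sigmoid fitting of object-count series
    with derived halving time, lag time and density fraction; the
    halving-time versus seeding-density scaling test that separates directed
    from random cluster motion; pseudo-volume growth fits and doubling
    times; cross-correlation frame alignment and symmetric-difference area
    velocities; and cytokine-array threshold selection with transwell
    fold-over-control statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
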