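Package: stonecellr
Title: Quantitative Histology of Stone Cell Clusters in Pear Fruit Flesh
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify stone cell (sclereid) clusters and parenchyma
    cells in stained sections of pear fruit flesh. Provides a synthetic
    stained-section generator with per-cell ground truth, hue-based stain
    separation into lignin and cell-wall channels, instance segmentation of
    stone cells (including partially lignified ring-stage cells) and
    parenchyma lumina, adjacency grouping of stone cells into clusters versus
    isolated cells, cell morphometry (area, Feret diameters, circularity),
    concentric-zone partitioning with area-weighted global aggregation,
    flesh-texture classification by cluster diameter, and the accompanying
    statistical stage (arcsine transformation, nested repeated-measures
    ANOVA with split-plot error strata, Tukey compact letter displays).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    withr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    car,
    EBImage,
    tiff,
    png,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
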