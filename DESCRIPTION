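Package: sdmtoolkit
Title: GIS-Free Toolkit for Species Distribution Model Workflows
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core for species distribution modelling workflows
    without a desktop GIS: ESRI ASCII raster handling and batch utilities,
    spatial rarefaction of occurrence records (single- and multi-distance),
    MaxEnt background/bias surface construction (buffered minimum convex
    polygon, distance buffers, Gaussian kernel density, buffered local
    adaptive convex hulls), spatially jackknifed model tuning and selection
    with omission-rate and AUC statistics, MaxEnt batch-file emission, SDM
    post-processing (binarisation, clade splitting, dispersal limitation),
    endemism and CANAPE biodiversity grids from binary range stacks and
    Biodiverse randomisation exports, and least-cost-path landscape
    connectivity. Ships seeded synthetic-data generators so every analysis
    is reproducible offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    pracma
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
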