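Package: mifscape
Title: Spatial Tumor Immune Microenvironment Analysis for Multiplex
    Immunofluorescence Cell Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the spatial tumor immune microenvironment (TiME)
    from segmented-cell tables exported by multiplex immunofluorescence
    (mIF) image analysis. Provides marker-threshold phenotyping into
    exclusive lineages and functional flags, maximum-density hotspot
    selection with per-phenotype densities (cells per mm^2) and two-factor
    group statistics, a 15 micrometre proximity graph with label-permutation
    interaction enrichment, and k-means clustering of k-nearest-neighbour
    neighbourhood composition profiles into cellular niches ("C-niches").
    A synthetic scene generator with planted ground truth (phenotype
    mixtures, attracted cell pairs, invasive-margin bands, spatial niches)
    makes every stage testable without access to patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
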