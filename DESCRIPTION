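Package: savcarbon
Title: Whole-Ecosystem Carbon Accounting for Disturbance-Prone Savannas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying whole-ecosystem carbon storage in
    disturbance-prone savanna landscapes. Converts growth-form stratified
    woody-plant inventories to aboveground carbon with disturbance-loss
    correction, estimates belowground root carbon through damage-adjusted,
    size-dependent root-to-shoot ratios, aggregates depth-resolved soil
    organic carbon stocks with vegetation-patch weighting, scores plot-level
    disturbance regimes and herbivore-guild densities, and analyses
    non-linear disturbance-carbon relationships with generalized additive
    mixed models using shrinkage (double-penalty) smoothness selection and
    hierarchical partitioning of explained deviance. Includes a synthetic
    plot-data generator emulating a two-vegetation-type, five-land-use
    design so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
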