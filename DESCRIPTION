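Package: urbancarbon
Title: Urban Forest Carbon Life-Cycle Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Life-cycle simulation of above-ground carbon in urban tree
    populations. Provides species-specific nonlinear diameter growth curves
    (Chapman-Richards and Gompertz) with closed-form age inversion, pluggable
    allometric biomass models and a fixed biomass-to-carbon fraction,
    stratified annual mortality over street, mixed and park land-use classes,
    a tree-planting scenario engine with population half-life analysis, an
    annual cradle-to-grave carbon accounting loop reporting alive and
    accumulated-dead pools at regular intervals, and a synthetic tree-inventory
    generator calibrated to published summary statistics of a large remotely
    sensed city inventory.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
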