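Package: hemocloud
Title: Point-Cloud Deep Learning Surrogate for Aneurysm Hemodynamics with
    Porous-Medium Flow-Diverter Stents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates parametric side-wall cerebral aneurysm geometries,
    synthesizes steady velocity and pressure fields before and after
    flow-diverting stent placement (the stent represented as a thin
    Darcy-Forchheimer porous layer across the aneurysm neck), extracts
    boundary (model) and interior (query) point clouds into four
    hemodynamic data sets, and trains a double-input point-cloud
    regression network that predicts per-point velocity or pressure from
    geometry alone.  Includes NMAE/MRE error functionals with region-wise
    (whole model vs. aneurysm sac) reporting, legacy-VTK and PLY point
    cloud serialization, and a seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
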