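Package: hierODR
Title: Cortical Hierarchy Inference from Laminar Optical Density Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the laminar termination patterns of interareal
    axonal projections as an optical density ratio (ODR; mean labeled-axon
    intensity in layers 2-4 over the summed means in layer 1 and layers
    2-4), and infers a continuous cortical hierarchy from a directed
    area-by-area ODR matrix.  Hierarchical levels are estimated by maximum
    likelihood beta regression of the ODR on an incidence-matrix design
    with a logit link and a common precision parameter; model selection
    over same-level area partitions uses AIC; directed pathways are
    classified feedforward, lateral, or feedback by Wald contrasts on the
    fitted levels.  Also provides model-free hierarchical distances from
    unit-slope pairs plots, reciprocity regressions for reciprocal pathway
    pairs, elliptical Gaussian receptive-field fitting with equal-area
    2-SD diameters, and a synthetic-data generator emulating the full
    tracing and recording data model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    pracma,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
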