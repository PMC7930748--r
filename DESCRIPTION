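Package: epimorph
Title: Epithelial Sheet Morphometry and Hierarchical Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric analysis of segmented epithelial monolayers such as
    retinal pigment epithelium flatmounts. Converts integer label images or
    polygon sets into per-cell shape metrics (area, perimeter, solidity, Feret
    diameters, moment-ellipse eccentricity and aspect ratio, neighbor counts,
    and 0-10 polygonality and hexagonality regularity scores), builds the cell
    neighbor graph, and compares genotype or treatment groups with linear mixed
    models that respect the cells-in-images-in-animals hierarchy, including a
    robust residual-from-median variance test, Bonferroni-Dunn correction and
    Tukey pairwise contrasts. Ships a synthetic epithelial sheet generator
    (jittered-lattice Voronoi tessellations with Lloyd relaxation) providing
    exact ground truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    tiff,
    png,
    e1071,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
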