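Package: vacuomorph
Title: Morphometry and Connectivity of Schlemm's Canal Inner-Wall Cells from
    Serial-Section Contour Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of 3D-reconstructed Schlemm's
    canal inner-wall (IW) endothelial cells traced from serial block-face
    electron microscopy stacks. Provides a labeled contour-stack data model
    with JSON and Reconstruct-XML readers, per-cell morphometry (length,
    segmented-line width, thickness, giant-vacuole-subtracted volume, and
    adjacent-cell overlap length under the 45-degree rule), classification of
    IW-to-juxtacanalicular connections (types 1-7 with height and contact-area
    thresholds) and giant-vacuole types (I-IV), pore validation, flow-area
    summary tables, and the associated ANOVA/Tukey and Kruskal-Wallis/Wilcoxon
    comparison statistics. A parametric synthetic-cell generator rasterizes
    cells with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
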