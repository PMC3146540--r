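Package: odcell
Title: Condition-Dependent Cell Volume and OD-Specific Cell Concentration
    of Escherichia coli
Version: 0.1.0
Authors@R:
    person("odcell", "maintainers", email = "odcell@example.org",
           role = c("aut", "cre"))
Description: Tools to convert optical-density-normalized population
    measurements of Escherichia coli into per-cell copy numbers and
    intracellular molar concentrations.  Ships a curated reference table
    of growth-condition-dependent cell length, width, single-cell volume,
    OD-specific cell concentration and OD-specific total cell volume;
    computes spherocylinder (capped-cylinder) volumes from microscopy
    morphometry; performs bead-referenced absolute cell counting from
    flow-cytometry event tables; fits growth-rate-dependent cell-volume
    and cell-concentration models; and propagates measurement uncertainty
    through the unit conversions.  Includes seeded synthetic generators
    for microscopy images, cytometry event tables, OD calibration pairs
    and omics tables so every pipeline stage is testable against known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
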