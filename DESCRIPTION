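Package: angioscreen
Title: Quantification and Plate-Level Quality Control for Perfused
    Microvessel Angiogenesis Screening Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end analysis of microfluidic 3D angiogenic sprouting
    assays: reading and stitching two-channel (nuclei, F-actin) confocal
    stacks, maximum-intensity projection, segmentation of sprouts and
    nuclei, per-chip sprouting metrics (total sprout area, migration
    distance of the furthest nuclei, nuclei count, total vessel length),
    plate-level assay-performance statistics (signal window, Z-factor,
    assay variability ratio, coefficients of variation) with screening
    acceptance criteria, and four-parameter logistic dose-response fits
    with bootstrap IC50 confidence intervals. Includes a ground-truthed
    synthetic chip-image and plate generator so the whole pipeline can be
    validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
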