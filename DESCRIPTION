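Package: cardioelast
Title: Tissue Elasticity Mapping from AFM and Depth-Sensing Nanoindentation
    Force Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for nanoindentation-based tissue elasticity
    mapping of soft biological samples such as regenerating zebrafish heart
    sections. Provides Hertzian contact-model fitting of force-distance
    curves for spherical (colloidal-probe AFM) and cono-spherical
    (large-displacement depth-sensing) indenters, including baseline
    correction and automatic contact-point detection; assembly of
    quantitative-imaging stiffness maps with pooled regional medians and the
    mean-of-medians section summary (E_final); synthetic generators for
    force curves, stiffness fields and histology section phantoms with known
    ground truth; histology-derived region classification and morphometry
    (nuclei densities, fibrin-band length/width, area and positive-cell
    fractions); and the accompanying inference layer (one-way ANOVA with
    Tukey's HSD, variance-ratio F test, t tests) implemented from first
    principles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
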