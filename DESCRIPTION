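Package: mitocme
Title: Quantitative Analysis of Mitotic Shutdown of Clathrin-Mediated Endocytosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for the quantitative assays used to
    study why clathrin-mediated endocytosis shuts down in mitosis under
    elevated plasma-membrane tension. Implements optical-trap tether-force
    measurement from bead-displacement traces (equipartition stiffness
    calibration, zero-reference baselines, one-second plateau averaging,
    tether-age and double-tether quality control, per-experiment relative
    forces); comparative label-free quantitation (LFQ) proteomics of
    clathrin-coated-structure fractions with Gaussian-histogram outlier
    calling at two fitted standard deviations and condition-exclusive
    classification; region-of-interest quantification of cortical versus
    cytoplasmic F-actin, cytoplasmic G-actin and transferrin uptake from
    fluorescence images; flow-cytometry uptake quantification (forward-scatter
    gating and FL1 geometric means); and the accompanying group statistics
    (Welch and Student t-tests, one-way ANOVA with Tukey's post-hoc test,
    mean and SEM summaries). A synthetic-data module generates every input
    type with recorded ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
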