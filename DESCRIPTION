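Package: tmesubtype
Title: Tumor-Microenvironment Subtyping from Multiplex Imaging Single-Cell Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cell-frequency-based tumor-microenvironment
    subtyping of multiplex-imaging single-cell data from triple-negative breast
    cancer tissue. Provides rule-based lineage gating (quality-control filtering,
    per-core background subtraction, threshold gating of endothelial, epithelial,
    immune and stromal cells), per-core composition profiling with graph-community
    subtyping into stromal-poor, stromal-rich-immune-rich and
    stromal-rich-immune-poor classes, periphery/border/core spatial compartment
    density analysis, centroid-correlation molecular subtype calling of bulk
    expression against BLIA/BLIS/LAR/MES signatures, and the accompanying survival
    and association statistics (Kaplan-Meier, weighted log-rank family,
    chi-squared, odds ratio). A synthetic cohort generator with known ground truth
    (cells with spatial geometry, paired bulk counts, survival records) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    igraph,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
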