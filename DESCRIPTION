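Package: spikeclean
Title: Spike-In Based Decontamination and Cell-Type Analysis for Droplet
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Droplet-based single-cell RNA-seq libraries carry cell-free
    ("ambient") RNA released by lysing cells, which is co-encapsulated with
    intact cells and can account for a large fraction of reads per cell.
    spikeclean implements a decontamination method built around cross-species
    spike-in reference cells: reads from spike-ins that align to the sample
    genome measure each spike-in's contamination fraction directly, a
    sample-level contamination signature is estimated by comparing
    contaminated spike-ins to clean references, per-cell contamination is
    predicted from the most contaminating marker genes with no-intercept
    linear models, and expression values are corrected by subtraction and
    renormalization. The package also provides marker-free cell-type
    assignment (hormone thresholds plus an L1-regularized multinomial
    classifier), two doublet filters, negative-binomial differential
    expression with cross-species fold-change comparison, and a fully
    ground-truthed two-species droplet simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
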