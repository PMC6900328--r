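Package: stableScreen
Title: Pan-Cancer Screening of Stable and Flexible Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rank-based screening of gene expression stability across multiple
    cancer cohorts against a shared control group. Computes per-gene per-group
    descriptive statistics (mean, standard deviation, coefficient of variation,
    log2 difference versus control), pooled Mann-Whitney U comparisons of each
    cancer group against control, percentile (0.1 percent) selection of genes
    with the lowest standard deviation, lowest or highest difference versus
    control, cross-cohort membership intersection with the per-gene
    group-index report format, the derived stable/flexible gene categories,
    within-group rank ("relative expression") summaries with consistency
    calls, and average-linkage Euclidean hierarchical clustering with Newick
    export. Includes a seeded synthetic multi-group cohort generator with
    planted stable-variance, flexible and shifted-stable gene classes plus a
    recovery-scoring harness, so the whole pipeline is testable without access
    to the original tumor expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
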