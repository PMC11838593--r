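Package: snconsensus
Title: Consensus Differential Expression and Likelihood-Based Cell Typing
    for Single-Nucleus RNA-seq Case/Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for stratified case/control single-nucleus
    RNA-seq studies: reproducible synthetic multi-donor cohort simulation with
    planted markers, differential expression effects and donor-level
    coordination structure; heuristic tail-based nucleus quality filtering;
    highly-variable-gene ranking with marker-retention elbow guidance;
    truncated PCA with stored transforms, a pluggable batch-correction hook and
    back-projection to corrected integer counts; cross-validated
    marker-likelihood cell typing against a marker-gene database; k-fold
    consensus negative-binomial Wald differential expression over donor-group
    contrasts with covariate designs; discovery of highly coordinated
    differentially-expressed-gene subclusters from cross-donor covariance;
    cell-type composition testing; gene-set overlap permutation tests; and
    Wilcoxon power simulations for sample-size and fold-count selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
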