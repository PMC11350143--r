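Package: admixbench
Title: Simulation and Benchmarking of Bulk Transcriptome Cell-Type
    Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained benchmarking pipeline for bulk RNA-seq
    cell-type deconvolution. Simulates purified immune/stromal/cancer
    expression profiles and single-cell count fixtures, draws ground-truth
    mixing proportions with grid-constrained broken-stick and hit-and-run
    Markov chain Monte Carlo samplers, mixes them into in silico admixtures
    (TPM and pseudo-count space), deconvolves them with reference-based
    (nu-SVR, constrained weighted least squares, Huber robust regression)
    and enrichment-based (marker mean/sum) baseline methods, and scores
    methods with hierarchical correlation scores, bootstrap Bayes factors,
    within-sample metrics, consensus-rank ensembles, spillover specificity,
    spike-in limits of detection, and cross-dataset effect models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    pracma,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
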