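Package: regmra
Title: Transcriptional Regulatory Network Inference and Master Regulator
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reverse-engineers transcription-factor (TF) regulons from
    gene-expression cohorts using mutual information with permutation
    filtering and data-processing-inequality pruning, and analyses the
    resulting regulatory network: master regulator enrichment against
    disease-versus-origin gene signatures, per-sample two-tailed regulon
    activity scores, agonist/antagonist regulon association maps,
    Kaplan-Meier survival stratification by regulon activity, and
    differential-methylation enrichment of regulons.  A synthetic-data
    generator plants known regulatory structure (two mutually antagonistic
    master-regulator clusters with opposite prognostic impact) so that
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
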