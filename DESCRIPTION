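Package: seromiR
Title: Serum miRNA Biomarker Discovery from Count Matrices
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for circulating (serum) miRNA
    biomarker discovery from small-RNA sequencing read counts: expression
    filtering, trimmed-mean-of-M-values (TMM) normalization, covariate-adjusted
    negative-binomial likelihood-ratio tests with Benjamini-Hochberg correction,
    PCA and silhouette-based cluster-number estimation under correlation
    distances, k-nearest-neighbour marker ranking with leave-one-out
    cross-validation and cumulative accuracy curves, bootstrap selection of k,
    two-sample t-test validation on independent expression tables, and
    hypergeometric target-gene set enrichment. A negative-binomial cohort
    simulator with planted differential expression and confounded covariates
    makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    fgsea,
    stats,
    utils,
    withr
Suggests:
    cluster,
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
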