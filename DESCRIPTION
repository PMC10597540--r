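Package: episubtype
Title: Outcome-Guided Molecular Subtype Discovery from Multimodal Transcriptomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers molecular subtypes of epilepsy associated with
    post-surgical seizure recurrence from blood and brain miRNA/mRNA
    expression. Implements batch-wise standardisation with near-zero-variance
    filtering, hierarchical clustering over a distance-by-linkage grid with
    iterative dendrogram splitting, covariate-adjusted logistic association of
    cluster membership with outcome and FDR-governed selection of the optimal
    clustering, bootstrap confidence intervals for cluster recurrence
    proportions, hypergeometric cross-modality cluster overlap tests,
    cluster-versus-rest differential expression with a shifted fold-change
    transform, preranked gene-set enrichment with custom signatures, and
    upstream miRNA regulator activation scoring against a target network.
    Includes a synthetic multimodal cohort generator with planted ground truth
    for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    caret
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
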