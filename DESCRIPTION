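Package: stagewave
Title: Stage-Resolved Proteogenomic Analysis of Tumor Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for stage-resolved proteogenomic analysis of tumor
    progression cohorts profiled across ordered histopathological
    (sub)stages: neo-mutation wave detection and phase partitioning of
    somatic mutation catalogs, 96-channel mutational-signature extraction
    by KL-divergence NMF with cophenetic rank selection and cosine matching
    to reference catalogs, APOBEC (TCW-motif) enrichment scoring, SCNA
    cis-effect correlation, FOT normalization and stage-wise differential
    expression of label-free proteomes, co-expression wave panels,
    significance analysis of microarrays (SAM) with permutation FDR,
    consensus clustering, match-between-runs retention-time imputation,
    kinase-substrate enrichment analysis (KSEA) of phosphoproteomes, and
    gene-set statistics (hypergeometric ORA and preranked GSEA). A
    synthetic cohort generator with known ground truth makes every stage
    of the pipeline testable without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
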