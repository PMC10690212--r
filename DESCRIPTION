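Package: moccanet
Title: Phenotype-Specific Multi-Omics Network Inference via Sparse
    Multiple Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers phenotype-specific multi-omics networks from one or more
    omics matrices measured on common subjects. Canonical feature weights are
    estimated by sparse multiple canonical correlation analysis (quantitative
    phenotypes) or a hybrid of phenotype-free sparse multiple CCA and sparse
    partial least squares discriminant analysis (binary phenotypes). A
    consensus feature similarity matrix is built by aggregating absolute
    outer products of canonical weights over feature subsamples, candidate
    modules are obtained by hierarchical tree cutting, and each module is
    pruned by a PageRank-ordered search that maximizes the correlation of a
    PCA or topology-aware (NetSHy) network summarization score with the
    phenotype. Includes k-fold cross-validation over penalty grids,
    automated scaling-factor selection, a synthetic data generator with
    planted cross-block latent structure, and an automated end-to-end
    pipeline with text-based result persistence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
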