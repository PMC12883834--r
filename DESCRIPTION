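Package: neuroselect
Title: Mapping Multigenic Evolutionary Selection onto Functional Brain Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated imaging-transcriptomics workflow that projects
    task-fMRI z-score maps onto brain-expression biopsy sites with a
    density-adaptive direct/Gaussian rule, correlates spatial gene expression
    with functional networks, groups networks into domains by Ward clustering
    with silhouette model selection, rank-normalizes branch-wise dN/dS
    (omega) tables and network correlations, mines the concatenated
    selection-by-correlation matrix with a seeded genetic-algorithm
    biclusterer (subpopulations, tabu masking, parameter cycling, post-hoc
    merging), and summarizes the resulting biclusters at network-domain and
    single-cell cluster level. Ships a synthetic-data generator with planted
    co-expression modules, planted high/low-omega gene pools and planted
    enriched cell types so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
biocViews: Transcriptomics, Clustering, GeneExpression, Phylogenetics
RoxygenNote: 7.3.3
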