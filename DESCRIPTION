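Package: csrtraits
Title: Genome-Resolved CSR Life-History Strategy Classification Across
    Disturbance Gradients
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies metagenome-assembled genomes (MAGs) and
    community-aggregated traits (CATs) into Grime's
    competitor/ruderal/stress-tolerant (CSR) life-history strategies across
    replicated disturbance-frequency gradients. Provides a Dirichlet-
    multinomial synthetic community generator with planted strategies, trait
    normalization and abundance-weighted community aggregation of COG
    functional categories, simulation-based regime enrichment testing with
    Benjamini-Hochberg control, distance-based multivariate statistics
    (square-root Bray-Curtis, PCoA, PERMANOVA, PERMDISP, CAP, DistLM with
    AICc stepwise selection, dbRDA, correlation-vector overlays, group-
    average similarity clustering), SparCC compositional correlation
    networks with Louvain module detection, and an end-to-end pipeline with
    tabular reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    igraph,
    vegan,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metagenomics, Microbiome, Software, StatisticalMethod
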