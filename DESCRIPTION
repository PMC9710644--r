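Package: hmsdiv
Title: Hierarchical Dissimilarity for Microbiome Functional Beta-Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Beta-diversity analysis of microbiome functional profiles
    (KO-style gene-family relative abundances) using a hierarchical
    dissimilarity: Bray-Curtis distances are computed at the gene-family
    level and at the three levels of a metabolic pathway hierarchy
    (KEGG BRITE style), then combined as a weighted mean. Includes
    deterministic parallel pairwise distance matrices, classical-MDS
    principal coordinates analysis, ANOSIM and Monte-Carlo Procrustes
    validation statistics, four benchmark distance metrics, synthetic
    profile generators reproducing two designed failure modes of
    flat (non-hierarchical) metrics, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'hierarchy.R'
    'profile-io.R'
    'hms-distance.R'
    'benchmark-distances.R'
    'pcoa.R'
    'validation-stats.R'
    'synthetic-data.R'
    'cli.R'
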