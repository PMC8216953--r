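Package: seagen
Title: Seascape Genomics of Larval Dispersal and Population Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A seascape-genomics toolkit for semi-enclosed ocean basins.
    Simulates Lagrangian larval dispersal over gridded surface-velocity
    fields with larval-trait behaviour (competency window, early mortality,
    radius-based settlement), derives directed population-by-population
    connectivity matrices and asymmetric eigenvector maps (AEM), generates
    synthetic metapopulation SNP panels with planted clinal outliers,
    replicates a post-assembly SNP filter cascade with per-step bookkeeping,
    and provides population-genetic estimators (Weir-Cockerham FST with
    resampling inference, hierarchical AMOVA, Mantel isolation-by-distance,
    linkage-disequilibrium effective population size, directional relative
    migration), FST-outlier scans (trimmed chi-square and island-model
    envelope with a two-method consensus rule), and constrained ordination
    (Hellinger-transformed allele frequencies, redundancy analysis with
    permutation inference and backward selection, environmental vector
    fitting, DAPC) linking genetic structure to ocean currents and
    environmental gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    igraph,
    MASS,
    vcfR,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
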