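Package: phyconet
Title: Core Microbiomes and Sparse Association Networks of Host-Associated Biofilms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of host-associated biofilm microbiomes from
    amplicon (ASV) count tables: core-microbiome and host-specific taxon
    extraction under prevalence/read/abundance thresholds, compositional
    community statistics (Shannon diversity, Bray-Curtis distances, PCoA,
    PERMANOVA with permutation or exact enumeration, beta-dispersion,
    pairwise tests), compositionally robust sparse association network
    inference (centered log-ratio transform, lasso neighborhood selection,
    StARS stability selection), network metric profiling with Zi-Pi
    hub/connector classification, and Euclidean comparison of network
    profiles. Includes a synthetic-data generator with a known sparse
    association graph and planted core/host-specific structure, and a
    deterministic end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    biomformat,
    glmnet,
    igraph,
    vegan,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
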