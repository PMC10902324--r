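Package: mlmod
Title: Multilayer Network Communities and Persistence Modules for
    Disease-Gene Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Community detection on multilayer gene networks by generalized
    Louvain maximization of a resolution-parametrized multilayer modularity,
    with a resolution sweep, extraction of persistence modules (groups of
    genes of interest that co-cluster across the resolution range), and
    randomization-based significance procedures for rare-disease cohort
    severity analysis: balanced-randomization validation of gene-set
    co-membership, severity-label-shuffling null distributions for module
    sizes, and exact association tests for clinical variables. Includes
    seeded generators for planted-partition multilayer networks, synthetic
    patient cohorts and gene-set catalogs, plus readers and writers for
    edge-list, GMT, cohort and partition interchange formats and a
    configuration-driven pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
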