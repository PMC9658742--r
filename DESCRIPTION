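Package: methylim
Title: Methylation-Driven Discovery of Immune Subgroups in Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers immune-related subgroups within a tumor cohort from
    promoter DNA methylation. The pipeline filters and imputes array beta
    values, calls differentially methylated sites against normal samples,
    detects co-methylation modules with a weighted correlation network
    (topological overlap), scores modules by their overlap with enriched
    pathway gene sets, selects feature sites with a shadow-feature
    (Boruta-style) random-forest procedure backed by a linear support vector
    machine classifier, and clusters samples on the resulting key genes.
    Companion tools build cell-type signature matrices from labeled single
    cells, deconvolve bulk expression into cell-type proportions with
    nu-support-vector regression, score cytolytic activity, and compare
    subgroups on survival, clinical stage and immune features. A synthetic
    cohort generator with planted subgroup structure makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    e1071,
    fgsea,
    graphics,
    grDevices,
    jsonlite,
    randomForest,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
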