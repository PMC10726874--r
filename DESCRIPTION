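Package: dualtarget
Title: Dual-Purpose Anti-Aging and Anti-Cancer Target Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering therapeutic targets
    that are promising against both aging and cancer. It calls sex-adjusted
    age-associated genes in healthy-tissue expression data (partial Pearson
    correlation plus an old-versus-young moderated-t contrast), scores pathway
    activation per comparison and forms a unidirectional multi-dataset
    consensus rolled up to main cellular processes, meta-analyzes per-dataset
    differential expression within each cancer (combined log fold change,
    Stouffer z, Benjamini-Hochberg FDR), prioritizes common cancer targets
    across ranked per-cancer lists, annotates targets with the twelve
    hallmarks of aging via Gene Ontology keyword matching, classifies targets
    into four lifespan-evidence groups with tumor-suppressor exclusion,
    nominates unexplored dual-purpose candidates by overlapping hypergeometric
    GO enrichments, and evaluates organismal lifespan assays with pooled
    Kaplan-Meier curves and logrank tests. A synthetic-data generator with
    planted truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    limma,
    stats,
    survival,
    utils,
    withr
Suggests:
    flexsurv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
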