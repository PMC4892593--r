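Package: crossmarker
Title: Cross-Cohort Consensus Selection of Case-Control Expression Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering marker genes shared across several
    case-control gene expression cohorts profiled on different microarray
    platforms. Probe-level matrices are collapsed to official gene symbols and
    restricted to the commonly profiled genes; each cohort is then analysed
    marginally (fold-change ranking, Welch t-tests, Benjamini-Hochberg FDR
    selection) and jointly (L1-penalised logistic regression); genes selected
    in at least m of n cohorts by a method are voted into consensus pools, and
    the common markers are the genes picked by both the marginal and the joint
    route. Includes a synthetic multi-cohort generator with planted
    differentially expressed genes for calibration and validation, plus local
    (offline) gene-set over-representation and protein-protein-interaction
    summaries for the resulting marker set.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
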