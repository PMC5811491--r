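Package: comorbnet
Title: Comorbidity Gene-Set Overlap, Enrichment and Interaction-Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the genetic architecture of two comorbid
    disorders from curated candidate-gene lists. Merges evidence-source gene
    lists into per-disease sets, performs hypergeometric over-representation
    analysis against GMT annotation collections (KEGG pathways, GO biological
    process) with Benjamini-Hochberg correction, contrasts the significant
    terms of the two diseases, builds seed-plus-first-neighbor subnetworks in
    a protein-protein interaction network, intersects them, and prioritizes
    new candidate genes by their degree to the shared disease genes
    (guilt-by-association). Includes a synthetic-data generator with planted
    enrichment and planted candidate hubs so every stage can be benchmarked
    against known ground truth, and a single-config pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
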