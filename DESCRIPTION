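Package: mirlipidnet
Title: MicroRNA-Lipid Disease Association Networks from Literature Co-Occurrence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines a corpus of literature abstracts for co-occurrences of
    microRNA and lipid-disease mentions, scores each miRNA-disease pair with a
    one-sided Fisher's exact test on the 2x2 abstract contingency table, builds
    the edge-weighted bipartite association network, extends significant
    miRNAs with target genes drawn from regulatory interaction networks
    (RegINs) under a source-overlap threshold, and tests the resulting target
    sets for Gene Ontology term overrepresentation with a right-sided
    hypergeometric test and Benjamini-Hochberg correction. A synthetic-data
    module generates corpora, RegINs and GO annotation fixtures with planted
    ground truth so the full pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
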