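Package: sympnet
Title: Symptom-Centered Network Pharmacology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for symptom-centered network pharmacology analysis of
    complex diseases such as ankylosing spondylitis. Builds symptom-associated
    gene sets from relevance-scored association tables, prioritizes genes by a
    five-metric node-centrality consensus (degree, betweenness, closeness, and
    binary- and confidence-weighted eigenvector centrality) over
    confidence-filtered protein-protein interaction networks, validates
    candidates against case-control expression data (fold change, two-tailed
    t-test, Benjamini-Hochberg FDR), quantifies drug-target network proximity
    with a permutation null and normal-CDF p-value, and performs hypergeometric
    pathway over-representation analysis on GMT gene sets. Includes seeded
    synthetic-data generators emulating the structure of the upstream
    resources, so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
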