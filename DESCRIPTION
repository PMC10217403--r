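Package: rettnet
Title: Seed-Gene Interactome Analysis for Rett Syndrome and Rett-Like Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses first-order protein-protein interaction
    networks around Rett syndrome (RTT) and Rett-syndrome-like (RTT-L) seed
    genes. Provides curated seed-gene catalog parsing, construction of the
    first-order interactome from IID-style interaction tables, degree,
    betweenness and closeness centralities with per-class summaries and hub
    ranking, tissue restriction by a Human-Protein-Atlas-style ordinal
    expression rule, seed-mediated sub-network extraction, common-interactor
    reporting, multi-source hypergeometric over-representation analysis with
    Bonferroni correction, and a synthetic interactome generator with planted
    structure so the whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
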