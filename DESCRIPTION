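Package: ceRNAscreen
Title: Programmed Cell Death ceRNA Network Screening and Hub Gene Consensus
Version: 0.1.0
Authors@R:
    person("ceRNAscreen", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for screening programmed cell death (PCD)
    related competing endogenous RNA (ceRNA) regulatory networks from
    two-group expression data. Provides an empirical-Bayes moderated
    t-statistic differential expression engine, cross-dataset intersection
    of differentially expressed genes with apoptosis, necroptosis and
    pyroptosis gene sets, hypergeometric over-representation analysis,
    consensus voting over multiple interaction-prediction sources,
    tripartite lncRNA-miRNA-mRNA network assembly, seven graph centrality
    algorithms (MCC, Degree, EPC, EcCentricity, Closeness, Radiality,
    Betweenness) with seven-way consensus hub extraction, regulatory-axis
    enumeration, and a synthetic-data generator with ground-truth sponge
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    xml2
Suggests:
    igraph,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
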