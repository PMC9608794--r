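Package: cernet
Title: Competing Endogenous RNA Network Inference from Shared miRNA Targeting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers lncRNA-mRNA competing endogenous RNA (ceRNA) networks from
    two-group expression profiles and miRNA-interaction tables. Provides
    quantile normalization and Welch-t differential expression with
    Benjamini-Hochberg control, a hypergeometric shared-miRNA test for every
    candidate lncRNA-mRNA pair, bipartite network assembly, degree and
    betweenness based hub-lncRNA selection, tripartite subnetwork extraction,
    and generic over-representation analysis against GMT gene-set collections.
    A seeded synthetic-data generator with planted differential expression and
    planted ceRNA pairs makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
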