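Package: lncImmNet
Title: Immune-Related lncRNA Discovery, Regulatory Networks and Immune
    Subtyping for Small Inflammation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies immune-related long non-coding RNAs (lncRNAs) from
    paired lncRNA/mRNA expression matrices by ranking all mRNAs per lncRNA
    with a correlation-derived rank score, running weighted
    Kolmogorov-Smirnov gene-set enrichment against immune gene-set
    categories, and converting enrichment p-values into the lncRES score.
    Also provides empirical-Bayes moderated-t differential expression,
    bipartite lncRNA-pathway network export (SIF/GraphML),
    subsampling-based consensus clustering for molecular subtype discovery,
    single-sample gene-set variation scores and marker-based immune-cell
    abundance scores, plus a seeded synthetic-data generator that plants
    known immune-related lncRNAs, differential genes and immune subtypes so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
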