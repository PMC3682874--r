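Package: cliquesum
Title: Clique-Clustering Summarization of Semantic Predication Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Condenses corpora of subject-predicate-object semantic
    predications (SemMedDB-style) into graph summaries. Uninformative,
    weakly connected and infrequent predications are removed with
    mean-plus-half-standard-deviation cutoffs on degree centrality and
    citation frequency, maximal cliques are enumerated in the condensed
    graph, and cliques are grouped into labeled themes by hierarchical
    clustering of the clique co-membership matrix with metapredication
    (semantic group / predicate group) labels. Includes cluster validity
    scoring (cohesion, separation, overall) against a silhouette-coefficient
    baseline, a MeSH-descriptor labeling evaluation, Pajek/GraphML export,
    and a seeded synthetic corpus generator with planted themes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
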