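Package: triplink
Title: Tripartite Network-Based Inference for ncRNA-Disease Association
    Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate associations between non-coding RNAs and
    diseases by propagating a resource through a tripartite
    ncRNA-target-disease network. A two-level transfer builds weight
    matrices between targets and between diseases, tuned by a pair of
    hybrid ProbS/HeatS exponents, and chains them through the
    target-disease adjacency into a recommendation score for every
    candidate pair. The package also provides the full cross-validated
    evaluation protocol (precision and recall enhancement against a null
    model, ROC/AUC, recovery, personalization, surprisal, Friedman
    comparison of methods) and a seeded generator of sparse, connected,
    approximately scale-free tripartite networks with optional planted
    block structure for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
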