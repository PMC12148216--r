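Package: kgsynergy
Title: Drug-Synergy Enrichment, Embedding and Repurposing on Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enriches a biomedical knowledge graph (a pharmacome: drugs,
    proteins, genes, pathologies connected by typed directed relations) with
    synergism and antagonism edges derived from high-throughput drug-combination
    screens harmonized on the zero-interaction-potency (ZIP) scale. Learns
    knowledge-graph embeddings (TransE, TransR, RotatE, ComplEx, HolE) under the
    stochastic local closed-world assumption, ranks candidate relation types
    between drug pairs, and evaluates rank-k true-prediction percentages and
    one-vs-rest macro ROC-AUC. Classifies drug pairs as synergistic or
    antagonistic with nested cross-validated classical learners on
    order-invariant topological, physicochemical and embedding features. Prunes
    the graph to its causal-only form, and nominates drug-repurposing candidates
    as safe synergistic partners of anchor drugs supported by shared pathways to
    the disease. Ships a synthetic-data generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    glmnet,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
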