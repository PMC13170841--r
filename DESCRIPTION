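Package: cmkg
Title: Cross-Medicine Knowledge Graphs for Interpretable Drug Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing typed cross-medicine knowledge
    graphs that bridge traditional-medicine entities (herbs, ingredients,
    syndromes) and modern-medicine entities (compounds, diseases, pathways)
    through shared gene targets. Provides tab-separated triple-store I/O with
    integrity checking, entity alignment and Jaccard/overlap relation fusion,
    four knowledge-graph embedding models (TransE, DistMult, ComplEx, RotatE)
    trained with margin-ranking loss and evaluated under the filtered
    MRR/Hits@K protocol, gene-bridged meta-path-constrained candidate ranking,
    a path-sampling Horn-rule miner with an AnyBURL-compatible rule dialect,
    and a unified mechanistic path scoring system combining a geometric-mean
    base score, a TF-IDF-style ingredient specificity index, hybrid
    rule/search confidence calibration, length decay and evidence bonuses,
    together with sensitivity and ablation harnesses and a seeded synthetic
    graph generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
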