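Package: fzhynet
Title: Network Pharmacology and Transcriptomics Target Prioritization for
    the Fuzheng Huayu Formula
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to prioritize protein targets of a multi-herb formula by
    integrating network pharmacology with transcriptomics. Starting from a
    herb-component catalog, compounds are mapped to candidate targets by
    fingerprint (Tanimoto) similarity against an annotated drug library and
    by docking-score filtering against per-protein co-crystal controls; the
    resulting compound-target (CTPI) bipartite network is combined with
    high-confidence protein-protein interactions and a differential-gene
    list from a two-condition expression comparison into a tripartite
    compound-target-differential-gene (CTPG) network. Targets that bridge
    compounds to differential-gene proteins are prioritized, and the
    prioritized set is characterized by hypergeometric over-representation
    analysis against pathway, GO and disease annotation collections. A
    seeded synthetic-universe generator with planted ground truth supports
    end-to-end benchmarking of every stage.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
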