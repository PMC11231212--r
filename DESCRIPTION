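Package: kgevidence
Title: Explainable Drug Repositioning over Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for explainable drug repositioning over typed biomedical
    knowledge graphs. Learns cyclic path rules bottom-up from triples in the
    anytime style of rule-based knowledge-base completion, applies them to rank
    candidate treatments for a disease, grounds rules into compound-to-disease
    evidence chains, and reduces the chain space with an automatic filtering
    cascade: a rule filter that drops uninformative rule shapes, a significant-
    path filter that prefers approved-treatment edges over weaker trial edges,
    a deductive path builder that completes the most specific chain a group of
    paths implies, and a gene/pathway filter driven by multi-source
    gene-disease-association voting and Fisher's exact pathway enrichment with
    Benjamini-Hochberg correction. Includes a seeded synthetic knowledge-graph
    generator with planted ground truth for end-to-end validation, and a
    command-line interface binding all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
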