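Package: ppimnet
Title: Memory-Network Extraction of Mutation-Affected Protein-Protein
    Interactions from Annotated Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A document-level relation extraction pipeline for
    protein-protein interactions affected by mutations (PPIm).  Candidate
    mention-pair instances are generated from PubTator-style annotated
    abstracts with rule-based distance filters, context windowing and
    masking; prior knowledge is encoded from interaction-database triples
    with TransE translation embeddings; a dual memory-network classifier
    with multi-hop attention and position-impact weighting scores each
    instance; a sentence-support rule and any-positive document
    aggregation produce final gene-ID pair predictions, scored with
    micro-averaged precision, recall and F1 under exact-match pair
    identity.  Includes a seeded synthetic-corpus generator so the whole
    pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
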