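Package: kgrex
Title: Knowledge-Graph-Augmented Relation Extraction for Drug-Drug
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a two-stage pipeline that extracts drug-drug
    interactions from text with the help of a heterogeneous pharmaceutical
    knowledge graph. Stage one embeds a typed knowledge graph (drugs,
    proteins, pathways, MeSH categories, ATC codes, plus textual and
    molecular-structure pseudo-nodes) by link prediction with TransE,
    DistMult, ComplEx or SimplE score functions, trained with a logistic
    loss and type-constrained negative sampling, and evaluates ranking
    quality with MRR and Hits at k. Stage two injects the frozen entity
    embeddings into a small transformer relation classifier through
    end-of-sentence entity markers that share position identifiers with
    the in-sentence drug mentions. Ships corpus readers for the
    DDIExtraction-2013 XML dialect and a normalized JSON dialect,
    mention-to-graph linking, micro precision/recall/F over the positive
    interaction classes, an approximate-randomization significance test,
    synthetic generators for planted knowledge graphs and templated
    corpora, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
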