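Package: gogo
Title: Gene Ontology Semantic Similarity from DAG Topology with
    Children-Count-Aware Edge Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes semantic similarity between Gene Ontology terms from
    the topology of the GO directed acyclic graphs, weighting the semantic
    contribution passed along each edge by the number of children of the
    ancestor term so that broad terms contribute less, in the spirit of
    information content but without requiring an annotation corpus (the
    GOGO measure). Includes the Wang topological baseline, corpus-based
    information content with Resnik and Lin similarities, gene-level
    functional similarity under five mixing strategies (Avg, Max, ABM,
    BMA, BMM), affinity-propagation clustering of genes by functional
    similarity, a Matthews-correlation-coefficient protocol for evaluating
    clusterings against reference pathways (including noise-gene
    injection), readers and writers for OBO 1.2 ontologies and GAF/TSV
    annotations, and seeded generators for synthetic ontologies and
    clustered annotation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
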