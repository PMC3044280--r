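Package: oranet
Title: Gene Set Over-Representation Analysis with Kappa-Weighted Annotation
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Over-representation analysis (ORA) of user gene lists against
    multi-category annotation collections, using Cohen's kappa as the
    enrichment score, exact hypergeometric p-values and Benjamini-Hochberg
    q-values.  Builds kappa-weighted annotation-relationship networks over
    the enriched terms and exports them in Cytoscape SIF, GraphML, MCL ABC
    and TSV formats.  Also provides gene identifier normalization to a
    canonical gene ID space, named gene-set algebra (union, intersection,
    subtraction), gene-set expansion along typed molecular networks
    (protein-protein interaction, TF-target, miRNA-target, drug-target),
    hierarchical (tree) grouping of enrichment results, a command-line
    interface, and a deterministic synthetic-fixture generator with planted
    enrichment for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
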