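Package: orcEvo
Title: Copy-Number Evolution of the Origin Recognition Complex Across Eukaryotes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the duplication and loss history of
    gene families (the ORC/CDC6 replication-initiation subunits in
    particular) on an annotated eukaryotic species tree. Provides Dollo
    constrained Sankoff parsimony for per-lineage event inference from leaf
    copy numbers, branch-class enrichment tests (parasitic and
    whole-genome-duplication lineages) built on exact hypergeometric,
    Mann-Whitney and Spearman statistics, hierarchical clustering of taxa
    by subunit configuration with genome-metric normalization, pairwise
    protein alignment with region-wise (PACT motif vs background)
    identity and similarity ratios, phylogenetic-placement orthology
    assignment, and a seeded synthetic-data generator for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    ape,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
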