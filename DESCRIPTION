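Package: traitatlas
Title: Trait-Based Comparative Genomics of Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an atlas of genetic traits across bacterial genomes and
    clusters it in both directions: genomes into Genome Functional Clusters
    (GFCs) and traits into Linked Trait Clusters (LTCs), using phi-coefficient
    similarity matrices with chi-square/FDR retention and exemplar-based
    affinity propagation clustering. Includes KEGG-style module completeness
    reconstruction from KO annotations with a one-missing-reaction tolerance,
    B-vitamin acquisition strategy classification (consumer, independent,
    flexible), taxonomic-coherence labelling of clusters, interaction-trait
    enrichment and genome-size expectation tests, 16S amplicon-to-genome
    mapping with a specificity index, temporal-synchrony testing of OTU
    pairs, and a seeded synthetic-data generator that plants recoverable
    cluster structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
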