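Package: trmnet
Title: Reconstruction of Transcriptional Regulatory Modules from
    Protein-Protein Interaction Networks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs cell type-specific transcriptional regulatory
    modules (TRMs) around ChIP-seq-profiled target transcription factors.
    Integrates position weight matrix libraries from multiple motif
    databases, replicate motif-enrichment consensus filtering, cell
    type-specific expression filtering, and physical protein-protein
    interaction networks. The core algorithm extracts the subnetwork of
    candidate factors connected to the target factor through bounded
    all-shortest-paths search, allowing a configurable number of bridge
    proteins. Also provides edge-based Jaccard comparison and hierarchical
    clustering of modules, hypergeometric annotation enrichment, and fully
    seeded synthetic-data generators for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'pwm-io.R'
    'mappings.R'
    'tfclass-obo.R'
    'expression.R'
    'candidates.R'
    'ppi.R'
    'trm.R'
    'compare.R'
    'enrich.R'
    'simulate.R'
    'pipeline.R'
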