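Package: operonclade
Title: Phylogenetic Clustering and Evolutionary Classification of
    Bacterial Polysaccharide Operons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies bacterial exopolysaccharide (EPS) operon locus
    families by threshold clustering of patristic distances with composite
    cluster-quality optimisation (proportion clustered, silhouette, Dunn
    index), reconstructs putative operons from homology hit coordinates
    using genomic-proximity rules, classifies five types of operon
    evolutionary events (locus loss, locus duplication, fusion,
    rearrangement, operon duplication) against a reference operon, assigns
    clade labels and clade-combination strings, and builds genomic-proximity
    networks over phylogenetic clusters for export to Cytoscape-compatible
    formats. Includes a simulator that plants operons, events and clade
    partitions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
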