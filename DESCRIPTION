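Package: dcna
Title: Difference Contact Network Analysis of Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-theoretical dissection of multi-state molecular dynamics
    ensembles of large biomolecular assemblies. Computes per-state residue
    contact probability maps, builds consensus residue networks whose edges are
    contacts stable across all functional states, partitions them into dynamic
    communities with a Girvan-Newman procedure driven by a modularity stopping
    rule, and quantifies conformational transitions as difference contact
    networks (per-edge and community-aggregated changes in contact
    probability). Also provides covariance-based community network analysis,
    B-factor and principal component profiling of global motions, mapping of
    disease mutations onto dynamic community interfaces, and a synthetic
    multi-state ensemble generator with planted community structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
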