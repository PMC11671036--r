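Package: confland
Title: Conformational Landscapes from Clustered Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for sampling alternative conformational states of
    metamorphic proteins with subsampled structure prediction. Clusters a
    protein's multiple sequence alignment with DBSCAN over one-hot encoded
    match columns, assembles per-cluster complex alignments (unpaired
    ligand merging with diagonal padding, or homooligomer copy
    duplication), routes jobs through a pluggable structure-predictor
    contract (a deterministic mock ships for testing), and classifies
    predicted models into active/inactive conformational states by segment
    RMSD to reference structures, ranking by predictor confidence (plDDT,
    ipTM) to summarise ligand-conditioned conformational landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
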