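Package: frlpsi
Title: Comparative Evolution of Far-Red-Light Photosystem I
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study the molecular evolution of far-red-light
    (FRL) photosystem I in cyanobacteria. Classifies paralog-group-specific
    residues from grouped multiple sequence alignments, reconstructs marginal
    ancestral sequences on a fixed phylogeny under empirical amino-acid
    substitution models, scores ancestral conservation of group-specific
    residues, maps residues onto structures, clusters them spatially, measures
    chlorophyll ring-plane rotations and hydrogen-bond geometry between
    superposed structures, and combines the evidence into rule-based ancestral
    chlorophyll-site calls. A synthetic-data module generates alignments with
    planted group-specific columns, sequences simulated down a known tree, and
    cofactor coordinate sets with known rotations, so that every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    bio3d,
    phangorn,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
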