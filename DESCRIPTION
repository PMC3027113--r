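Package: psnsap
Title: Protein Structure Network Features for Classifying Amino Acid
    Substitutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds residue interaction networks from protein structures
    (side-chain centroid contacts within a distance cutoff), computes network
    topological features (degree, clustering coefficient, closeness,
    length-scaled betweenness), conservation features from PSI-BLAST sequence
    profiles (position-specific scores, observed frequencies, Shannon entropy),
    and a 25-dimensional encoding of the most conserved contact neighbors of a
    mutation site. These features feed a random-forest classifier that
    separates disease-associated from neutral single amino acid polymorphisms
    (SAPs), with grid-searched hyperparameters, stratified cross-validation,
    and permutation feature importance. A synthetic-data generator emits
    structures, profiles and labeled variant tables with planted signal so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    Biostrings
Config/testthat/edition: 3
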