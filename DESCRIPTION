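Package: aanet
Title: Weighted Amino Acid Networks with Similar and Dissimilar Link Weights
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds residue interaction networks from protein structures in
    PDB format, with nodes at side-chain geometric centers and links weighted
    by an inter-residue contact potential that carries both attractive
    (similar) and repulsive (dissimilar) weights. Provides three weight-to-
    distance conversions, weighted graph metrics (strength, weighted
    clustering, average shortest path length, betweenness with Z-scores),
    small-world assessment against size-matched random baselines, per-frame
    profiling of conformer series, and betweenness-based hot-spot
    identification with atom-contact classification for protein-drug
    complexes. Includes a deterministic synthetic-structure generator
    (compact chains, expansion series, toy complexes) so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
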