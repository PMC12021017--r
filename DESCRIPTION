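Package: enzgraph
Title: Structure-Aware Prediction of Enzyme Kinetic Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting enzyme kinetic parameters (kcat, Km) from
    protein sequence, protein structure and substrate information. Builds
    residue-level protein graphs from PDB backbones with rigid-motion
    invariant geometric features (RBF distance encoding, local frames,
    relative-orientation quaternions, sinusoidal positional encodings),
    encodes them with an edge-augmented multi-head graph-Transformer,
    fuses sequence, structure and substrate embeddings through a residual
    MLP reducer, and fits an extremely-randomized-trees regression head.
    Includes a data-curation pipeline for kinetic records (filtering,
    deduplication with maximum-value retention, mutation application,
    PDB chain selection by global-alignment identity, resolution
    filtering, seeded splits, sequence-similarity binning), evaluation
    metrics with grouped reporting, attention-based mutation-site
    profiling, and deterministic fixture generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ranger,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
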