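Package: rnaconsensus
Title: Consensus Scoring of RNA 3D Structure Ensembles with Base-Pair Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-model quality assessment for ensembles of RNA 3D structure
    decoys. For every pair of decoys the package computes an alignment-based
    global fold similarity (TM-score, with an iterative fragment-seeded
    superposition search) and a base-pairing agreement score (Interaction
    Network Fidelity, the geometric mean of base-pair precision and recall).
    The element-wise product of the two pairwise similarity matrices yields a
    consensus matrix whose off-diagonal row means are per-decoy quality
    scores: decoys consistently supported by both the 3D fold and the 2D
    base-pairing pattern of the ensemble score highest. Includes a geometric
    base-pair annotator, readers for PDB/mmCIF structures and external
    pair-list annotations, a CASP-style evaluation harness (composite ground
    truth, per-target min-max normalization, global and per-target
    Pearson/Spearman correlations with Fisher-z averaging, top-1 loss), and a
    synthetic decoy generator with known ground-truth quality for closed-loop
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    optparse,
    parallel,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
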