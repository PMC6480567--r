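Package: irdl
Title: Iterative Residue Docking and Linking for Peptide-Protein Binding Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the binding mode of short linear peptides in a rigid
    protein cavity by fragment growing: the peptide is split into short
    segments (each with at most ten rotatable bonds), the C-terminal segment
    is docked first, and the remaining segments are docked under a covalent
    proximity restraint and fused to the growing chain by in-silico amide bond
    formation, followed by clustering, rescoring and ranking of the
    reconstructed full-peptide poses. Ships a grid-based surrogate scoring
    function, a torsion-sampling conformer generator, pose-quality metrics
    (backbone and whole-peptide heavy-atom RMSD, rank of first correct pose,
    hydrogen-bond conservation ratio) and a synthetic pocket generator so the
    whole protocol is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
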