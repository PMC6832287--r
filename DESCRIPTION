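Package: s1scape
Title: Cross-Kingdom Comparative Analysis of S1 (OB-Fold) Domains
Version: 0.1.0
Authors@R:
    person("s1scape", "developers", email = "s1scape@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for comparative analysis of S1 domains,
    the RNA-binding variant of the OB-fold, across Bacteria, Eukaryota and
    Archaea. Parses PDB coordinate files, slices annotated domain regions,
    computes Needleman-Wunsch global alignments and percent-identity
    matrices, progressive multiple alignments and information-content
    sequence logos, Kabsch rigid-body superpositions and RMSD matrices,
    radii of gyration, per-residue flexibility classification from
    predicted fluctuations or B-factor z-scores, order/disorder-promoting
    residue composition, Kruskal-Wallis cross-kingdom comparisons, and
    UPGMA dendrograms from identity distances. Includes a synthetic-fixture
    generator with exact ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
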