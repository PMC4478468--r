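Package: ppaomp
Title: Structural Feature Prediction from Sequence Profiles and
    Profile-Profile Alignment for Outer Membrane Protein Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts one-dimensional structural features of proteins
    (three-state secondary structure, relative solvent accessibility,
    residue depth and the backbone Phi torsion angle) from PSI-BLAST
    position-specific scoring and frequency matrices using feed-forward
    neural networks trained by backpropagation with momentum. The
    predicted features are combined with the sequence profiles in a
    composite scoring function for affine-gap local and global
    profile-to-profile alignment, and an alignment-score decision layer
    classifies query sequences as beta-barrel outer membrane proteins by
    searching them against a feature-annotated profile library. Includes
    a seeded synthetic-family generator that emulates homologous sequence
    families with ground-truth structural labels so that every stage can
    be trained and evaluated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
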