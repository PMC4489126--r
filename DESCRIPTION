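Package: famsubmat
Title: Family-Specific Amino Acid Substitution Matrices from Alignment Blocks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds BLOSUM-style log-odds amino acid substitution matrices from
    curated multiple-alignment blocks of a single protein family, as done for
    the transmembrane segments of class A (rhodopsin-like) G protein-coupled
    receptors. Implements pair-frequency counting over block columns, observed
    and expected pair probabilities, half-bit log-odds scores and relative
    entropy, together with composition and per-column conservation statistics,
    matrix comparison (difference matrices, UPGMA residue clustering, classical
    multidimensional scaling), a matrix-driven global/local pairwise aligner
    with affine gap penalties, and a seeded synthetic-alignment generator for
    validation and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
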