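Package: submat
Title: Log-Odds Amino-Acid Substitution Matrices from Curated Seed Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs integer log-odds amino-acid substitution matrices
    from gapped, manually curated seed multiple sequence alignments.
    Implements identity-threshold sequence clustering with cluster-weighted
    pair counting, gap-pair exclusion, equal redistribution of ambiguous
    residue codes (B, J, Z, X) over their canonical expansions with a
    double-counting correction, per-group normalization, and rounded
    base-2 log-odds scoring with relative-entropy and expected-score
    diagnostics. Also provides homology-search benchmark statistics
    (coverage at a fixed errors-per-query budget, concerted Bayesian
    bootstrap, Z-scores) and the q-score alignment quality measure, plus
    a synthetic seed-alignment generator with known ground-truth
    substitution structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
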