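Package: profiledock
Title: Multi-Target Docking Re-Ranking and Kinase Similarity Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-ranks structure-based virtual screening results against
    kinase selectivity profiles that combine targets and anti-targets.
    Per-kinase docking ranks are aggregated over structures on a log
    scale, anti-target ranks are inverted, and a combined profile score
    penalising both poor average rank and unbalanced rank spread is used
    to re-order candidate molecules. The package also computes four
    kinase binding-site similarity measures from desk-scale inputs:
    ligand-profile similarity and promiscuity from bioactivity tables,
    pocket-sequence identity over the fixed 85-position binding-site
    alignment, interaction-fingerprint Tanimoto similarity with
    structure-quality filtering, and docking-rank similarity from the
    Spearman correlation of top-list intersections. A synthetic-data
    generator produces docking runs with controlled rank correlation,
    bioactivity tables with exact planned counts, mutated pocket
    sequences and noisy interaction fingerprints, so the whole pipeline
    runs and is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
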