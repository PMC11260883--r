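Package: barcodegap
Title: Local and Global DNA Barcoding Gap Analysis for COI Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the reliability of DNA barcoding for species
    identification and discovery from aligned mitochondrial COI sequences.
    Builds haplotype-aware datasets (unique-haplotype and all-sequence views),
    computes Kimura two-parameter distances with pairwise deletion, detects
    local (per-species) and global (per-genus) barcoding gaps with
    configurable threshold multipliers, selects minimum sample sizes by
    subsampling convergence, compares parallel datasets with permutation
    tests, performs distance-based species delimitation with average-rank
    partition scoring, and classifies recognized species against delimited
    partitions into five taxonomy-concordance categories. Includes a
    transition/transversion-aware sequence simulator so every stage can be
    exercised on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
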