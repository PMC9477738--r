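Package: cobind
Title: Peak Architecture and Co-Regulation Analysis for Cooperating Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how two transcription factors cooperate at
    shared genomic targets, modelled on the joint action of a bHLH factor
    binding G-boxes (CACGTG) and a single zinc-finger DOF factor binding
    [T/A]AAAG motifs. Implements peak-to-gene assignment with configurable
    upstream/downstream windows, metagene positional profiles against a
    randomized length-matched peak-set null envelope, consensus-motif
    scanning with per-peak count and consecutive-spacing statistics,
    central motif enrichment, binding-strength stratification by motif
    count (Kruskal-Wallis with pairwise Wilcoxon rank-sum tests and a
    compact letter display), differential peak occupancy from replicated
    count matrices, and the gene-set intersections that define a
    cooperatively regulated gene list. A synthetic-data generator plants
    motif architecture, occupancy effects and differential-expression
    structure with a full ground-truth record, so every analysis stage is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
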