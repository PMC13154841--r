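Package: circleBench
Title: Benchmarking Toolkit for Circular DNA and RNA Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the quality of eccDNA and circRNA detection
    from short-read sequencing. Provides a paired-end read simulator for
    circular and linear templates with ground-truth output, split-read and
    overlap filtering of predicted circles, multi-tool combination strategies
    (Union, Rosette, Intersect, Double, Unique) over threshold-clustered
    circle sets, precision/recall/F-score benchmarking against simulated
    truth, repeat and genomic element stratification, and a junction
    read-imbalance statistic (deltaCJ) with mappability-corrected,
    MAPQ-weighted binomial significance testing for evaluating circle calls
    without ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'circles.R'
    'filters.R'
    'combine.R'
    'metrics.R'
    'deltacj.R'
    'simulate.R'
    'io.R'
    'alignment-sources.R'
    'annotate.R'
    'circleBench-package.R'
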