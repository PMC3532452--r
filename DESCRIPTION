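Package: frcurve
Title: Reference-Free Assembly Evaluation with Feature Response Curves
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluates de novo genome assemblies without a reference sequence.
    Read-pair alignments from a paired-end library and, optionally, a mate-pair
    library are turned into per-contig coverage, spanning-coverage and
    insert-size tracks; fourteen alignment-derived mis-assembly features
    (coverage anomalies, compression/expansion statistics, mate-pair happiness
    violations) are called as typed suspicious regions and summarised as global
    and per-feature Feature Response Curves. A synthetic benchmark module
    generates reference genomes, typed mis-assembly events with a ground-truth
    ledger, simulated read pairs and liftover alignments, so that feature
    sensitivity and specificity can be measured hermetically.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
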