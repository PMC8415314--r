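Package: cnvmeann
Title: Copy Number Variation Calling from Read Depth with a
    Mind-Evolutionary-Algorithm-Trained Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects copy number variations (CNVs) from next-generation
    sequencing alignments by dividing the genome into fixed-size bins,
    extracting three per-bin features (read depth, GC-content and mean
    mapping quality), and classifying every bin into one of four copy
    number states (normal, gain, hemizygous loss, homozygous loss) with a
    small feedforward neural network.  The network's weights and
    thresholds are initialized by a mind evolutionary algorithm
    (similartaxis within superior/temporary subgroups, dissimilation
    between them) and refined by backpropagation.  Candidate bins are
    merged into CNV calls and can be benchmarked against ground truth by
    sensitivity, precision, F1-score and boundary bias.  Includes a
    feature-level simulator of tumor read-depth profiles with planted
    CNVs at configurable purity and coverage for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
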