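Package: anchorsplice
Title: Annotation-Free Detection of Splice Junctions and Small Indels from
    Split-Read Anchors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: De novo detection of splice junctions, small insertions and
    deletions from short single-end RNA-seq reads, without any gene
    annotation. Each read is split into two fixed-length anchors that are
    aligned independently to the genome and extended as far as they match;
    reads whose two halves land on non-contiguous loci define candidate
    breakpoint pairs, which are rescued, clustered by genomic coordinate,
    thresholded on uniquely positioned read support, and classified as
    splice junction, insertion, deletion, or other rearrangement. A
    uniform-placement null model provides a false-discovery-rate estimate
    for distance-stratified junction calls, and a built-in simulator
    generates genomes, gene models, variant-bearing transcripts and reads
    with a machine-readable truth table so every stage can be tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
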