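Package: occumap
Title: Spike-In Normalized ChIP-Seq Occupancy Profiling Around Gene Anchors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying protein occupancy on transcribed genes from
    aligned ChIP-seq reads. Implements spike-in normalization to reads-per-million
    tracks, subtraction of no-tag (or deletion-strain) background, replicate
    averaging, gene classification by length and by expression tier,
    strand-aware TSS/TTS-anchored signal matrices and metagene profiles, and
    windowed per-gene RPKM quantification. Includes a synthetic-data module
    that simulates annotations and single-end reads (with a foreign-genome
    spike-in) under parametric occupancy landscapes, so that every pipeline
    stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
biocViews: ChIPSeq, Coverage, Normalization, Epigenetics, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
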