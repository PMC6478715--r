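Package: meripkit
Title: Transcript-Coordinate MeRIP-Seq Peak Calling, mRNA Decay Kinetics and
    Translation Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for transcriptome-level N6-methyladenosine
    (m6A) profiling and its downstream readouts. Implements a sliding-window
    MeRIP-seq peak caller on longest-isoform transcript coordinates with a
    conditional beta-binomial enrichment test, gene-median normalization and
    replicate intersection; metagene and DRACH/GGACU motif summaries;
    actinomycin-D mRNA half-life estimation with ERCC spike-in calibration;
    ribosome-profiling translation efficiency; Audic-Claverie count
    statistics and fold-change filtering; and a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
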