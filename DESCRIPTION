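Package: divtx
Title: Motif-Anchored Quantification of Divergent Noncoding Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Strand-separated, windowed quantification of RNA-seq and TSS-seq
    signal around transcription-factor binding sites, for studying divergent
    (bidirectional) noncoding transcription at gene promoters. Provides
    anchor and window bookkeeping on 0-based half-open coordinates,
    QC filtering of paired-end stranded RNA-seq, single-end TSS-seq and
    MNase-seq alignments, strand-aware fragment counting, median-of-ratios
    transcriptome normalization with a transparent pseudocount fold-change
    estimator and threshold classification, 5-prime-end per-million track
    construction with TSS cluster calling and nearest-TSS distance
    statistics, anchor-centered signal matrices with k-means clustering and
    metagene profiles (including smoothed MNase coverage), and a
    ground-truthed synthetic-data generator producing SAM-format reads with
    planted divergent initiation fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    jsonlite
Config/testthat/edition: 3
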