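Package: startshift
Title: Detection of Ectopic Transcription Initiation, Promoter Nucleosome
    Encroachment, and Upstream Translation from Multi-Omics Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantifying transcription-start-site (TSS)
    fidelity after loss of a promoter-bound transcription factor. Builds
    strand-specific signal tracks from capped-RNA 5' end data (Start-Seq),
    MNase-Seq fragment centers and ATAC-Seq insertion sites; resolves
    observed TSSs from control Start-Seq; anchors cross-sample normalization
    on synthetic capped spike-in RNAs (regression factors and
    median-of-ratios size factors); detects ectopic initiation per gene with
    a binned negative-binomial differential test; classifies promoter
    nucleosome encroachment from MNase fragment-center occupancy; scores
    ribosome-profiling P-site triplet periodicity and upstream-ORF usage in
    ectopically transcribed regions; and extracts promoter sequence features
    (CCAAT boxes, YR initiators, conservation profiles). Includes a
    synthetic multi-omics data generator with full ground truth so every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
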