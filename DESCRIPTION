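Package: g4meth
Title: Integration of DNA Methylation, G-Quadruplex Signal, Chromatin
    Accessibility and Expression Around Transcription Start Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide integration of 5-methylcytosine (5mC) methylation,
    G-quadruplex (G4) CUT&Tag signal, ATAC-seq chromatin accessibility and
    RNA-seq differential expression. Provides canonical putative
    quadruplex-forming sequence (PQS) scanning, per-CpG and windowed
    methylation-level computation with hyper/hypomethylated transcript
    selection, TSS-anchored binned signal matrices with density-ratio
    statistics, accessibility-by-methylation stratification of PQS-level G4
    signal, MAnorm-style selection of non-differential ATAC peaks,
    per-chromosome knockout-versus-wildtype signal ratios, and linkage of
    upregulated genes to promoter G4 gains. A coupled synthetic multi-omics
    generator (methylation inhibits G4 formation, accessibility weakly
    promotes it, promoter G4s elevate transcription) exercises every stage
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
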