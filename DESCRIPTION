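Package: plastidnc
Title: Discovery of Chloroplast Noncoding and Antisense RNAs from
    Strand-Specific RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Threshold-based discovery of noncoding RNA (ncRNA) candidates
    from strand-specific RNA-seq of the chloroplast (plastid) transcriptome.
    Turns stranded read placements into per-base depth and read-start tracks,
    calls candidate transcripts with a 50x trigger / 10x end rule, unifies
    calls across genotypes with wild-type end precedence, classifies
    candidates against a gene annotation (antisense versus intergenic within
    gene clusters), quantifies per-genotype abundance by read-start binning
    (counts per million), scans candidates for small open reading frames, and
    simulates toy plastome transcriptomes with planted ground truth
    (read-through transcription, antisense amplification in a ribonuclease
    mutant, ligation end bias) for recovery benchmarking. Ships a packaged
    107-row candidate catalog used as a reference fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    GenomeInfoDb,
    jsonlite
Config/testthat/edition: 3
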