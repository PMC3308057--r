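Package: capeval
Title: Exome Capture Evaluation and Allele-Quality-Ratio Variant Recalling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating targeted (exome) capture sequencing
    experiments and for re-calling genotypes with allele-quality ratios.
    Provides interval algebra over capture designs and exon annotations
    (merge, flank, common-target intersection, design membership, GC content,
    mapability), FASTQ read cleanup (B-block trimming, pair length filtering,
    quality-encoding conversion, duplicate marking, seeded downsampling), a
    per-position pileup engine with read-boundary and soft-clip annotation,
    quality-ratio SNV recalling with heterozygous/homozygous banding, read-end
    anomaly (REA) detection, capture performance metrics (on-target fractions,
    threshold coverage, transcript completeness, GC-stratified coverage,
    allele balance, variant sharing, SNP-chip concordance), and a seeded
    synthetic-data generator that emulates targeted capture with off-target
    spillover, PCR duplicates, reference-biased allele sampling, GC-dependent
    coverage depression, low-quality read tails and planted read-end
    anomalies, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    XVector,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
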