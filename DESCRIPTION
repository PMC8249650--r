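Package: strainprofiler
Title: Replication, Small-RNA and Co-Expression Profiling of Probiotic
    Strains from Metagenomic and Metatranscriptomic Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to profile the in vivo activity of a sequenced bacterial
    strain from shotgun metagenomic and strand-specific metatranscriptomic
    data. Estimates population replication rates as the peak-to-trough ratio
    (PTR) of smoothed genome coverage around a GC-skew-predicted replication
    origin, calls candidate small regulatory RNAs as strand-aware coverage
    peaks in intragenic, intergenic and antisense regions with cross-stage
    merging, quantifies strain-specific abundance from uniquely aligned reads
    (RPKM, TPM, taxonomic roll-ups), and detects co-expression modules with
    eigengenes and hypergeometric pathway enrichment. Ships simulators for
    every input (skewed circular genomes, replication coverage gradients,
    stranded RNA-seq tracks with planted peaks, expression matrices with
    planted modules) so the whole pipeline is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
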