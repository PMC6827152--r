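Package: genomesurvey
Title: Genome Survey Sequencing Analysis: K-Mer Spectra, Assembly
    Statistics, GC-Depth Profiles and Microsatellite Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for draft-genome survey sequencing of non-model
    organisms. Filters paired-end short reads and reports quality
    statistics (Q20/Q30, per-base error rate, GC content), counts
    canonical k-mers exactly and estimates genome size, heterozygosity
    ratio and repeat ratio from the k-mer depth spectrum, computes
    contig/scaffold assembly statistics (N50/N90), profiles GC content
    against sequencing depth in genomic windows, and mines perfect
    di- to hexa-nucleotide microsatellites (SSRs). Includes a diploid
    read simulator with known ground truth so every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    rtracklayer
Config/testthat/edition: 3
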