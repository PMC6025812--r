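Package: ampliphase
Title: Haplotype Inference for Polyploids from Double-Barcoded PCR Amplicons
Version: 1.0.0
Authors@R:
    person("Ampliphase", "Developers", email = "ampliphase@example.org",
           role = c("aut", "cre"))
Description: Processes demultiplexed paired-end amplicon FASTQ files into
    per-locus sequence sets, clusters them into putative haplotypes with
    two-parent chimera filtering, and infers phased haplotypes for diploids,
    polyploids and samples of unknown ploidy.  Known ploidies are handled by
    maximising a multinomial likelihood over the integer partitions of the
    ploidy (allele dosages); unknown ploidies by a real-versus-error
    likelihood scan over the size-sorted clusters with a relative-increase
    cutoff.  Includes sliding-window quality trimming, paired-read overlap
    merging with an artificial N-join fallback, per-locus error estimation
    from PHRED scores, an internal center-star aligner with column-occupancy
    cleaning, and a ground-truth synthetic read simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
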