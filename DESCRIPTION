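Package: orgextract
Title: Reference-Free Extraction of Organelle Genomes from Whole-Genome
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Maja", "Lindqvist", email = "maja.lindqvist@example.org",
           role = c("aut", "cre"))
Description: Identifies and assembles high-copy-number organelle genomes
    (mitochondria, plastids) directly from whole-genome shotgun reads,
    without any reference or seed sequence. A nuclear depth threshold is
    estimated from the trimmed mean of per-base coverage over the longest
    assembled contig; reads carrying any k-mer whose pool-wide frequency
    exceeds the threshold are binned using a Count-Min Sketch, whose
    one-sided (overestimate-only) error guarantees that no qualifying read
    is lost, then assembled with a built-in iterative-k de Bruijn unitig
    assembler. The candidate contig is circularity-trimmed and validated by
    comparing its read depth with the nuclear background. A paired-end read
    simulator with a circular organelle at configurable copy ratio supports
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
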