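Package: pocpr
Title: Percentage of Conserved Proteins for Prokaryotic Genus Delineation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Percentage of Conserved Proteins (POCP), a
    genome-based similarity index used to assess genus boundaries in
    prokaryotic taxonomy. Proteomes are compared by bidirectional
    all-vs-all local protein alignment; proteins with a hit at e-value
    below 1e-5, identity above 40 percent and an alignable query region
    above 50 percent are counted as conserved, and POCP is the conserved
    count of both genomes divided by their summed proteome sizes. Ships a
    built-in Smith-Waterman aligner with affine gaps and Karlin-Altschul
    e-value estimates, a reader for precomputed BLAST/DIAMOND tabular hit
    files, all-vs-all and one-vs-all matrix modes with summary
    statistics, tab-separated outputs, and a synthetic proteome
    generator with a controlled shared-protein fraction for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
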