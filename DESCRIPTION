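Package: phaseflip
Title: Detection and Quantification of Invertible Promoter Phase Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying programmed DNA inversion of promoter regions
    in bacterial genomes and its consequences for phage-host population
    dynamics. Discovers candidate invertible loci as perfect inverted-repeat
    pairs with bounded spacers, quantifies per-locus ON/OFF orientation
    fractions in a cell population from paired-end reads by competitive
    alignment against dual orientation references, detects within-read
    rearrangements and recombination hotspots from long-read split
    alignments, and computes phage-host quantitative metrics: length
    normalised virus-to-microbe ratios, per-capita one-step growth analysis
    with multi-burst changepoint detection, adsorption rate constants, and
    plating / centre-of-infection efficiencies. Includes a synthetic-data
    generator producing genomes with planted invertible loci, mixed
    orientation cell populations, short paired and long reads, and host
    phage metagenome mixtures with machine-readable truth, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
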