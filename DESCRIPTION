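Package: mutaccum
Title: Mutation-Accumulation Analysis for Isogenic Cell-Line Cohorts
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for mutation-accumulation experiments in
    isogenic cell-line cohorts sequenced at moderate (20-30x) coverage.
    Calls sample-private (unique) single-nucleotide variants and short
    indels by simultaneous comparison of all samples at each genomic
    position, builds 96-triplet mutation spectra with genome
    triplet-frequency normalization, correlates spectra with a
    30-signature catalogue after cross-genome adjustment, classifies
    deletions by breakpoint sequence context (tandem repeat,
    microhomology, other), and provides the exact and t-based statistics
    used to compare genotype groups. Includes a synthetic-cohort
    generator (reference genomes, implanted private mutations, noisy
    pileup counts) so the whole pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
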