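Package: pvlas
Title: Present-Value Look-Ahead Genomic Selection and Breeding-Program
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating multi-generation genomic-selection
    breeding programs on phased biallelic marker data. Implements
    conventional truncation selection (CGS), look-ahead selection (LAS),
    and present-value look-ahead selection (PV-LAS), which chooses S
    crosses by maximizing the discounted sum of gamma-quantile genetic
    gains anticipated over a sliding look-ahead window. Includes a Markov
    recombination model of meiosis with an exact enumeration oracle, a
    descendant-gamete simulator with generation-inflated recombination
    frequencies, SNP-to-block aggregation, a pair-replacement local-search
    optimizer with an exhaustive oracle for small instances, synthetic
    founder/effect/map generators, file-format readers and writers
    (phased VCF, haplotype/effects/map TSV), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
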