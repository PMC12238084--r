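Package: repeatprobe
Title: Repeat-Based Oligo-FISH Probe Design and In-Silico Karyotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing oligonucleotide fluorescence in situ
    hybridization (FISH) probes from the tandem-repeat landscape of a genome
    assembly and for in-silico karyotyping with those probes. Detects tandem
    repeat arrays with a wraparound dynamic-programming scoring model,
    de-overlaps and filters them, collapses consensus monomers by greedy
    identity clustering, tiles and selects oligo probes under composition
    constraints, maps probes back onto chromosomes with explicit locus-calling
    thresholds, renders idiograms as SVG, and compares karyotype signal-site
    tables between accessions, including summary-statistic comparisons from
    published group means. A seeded synthetic-genome generator with planted
    repeat arrays and a truth BED supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
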