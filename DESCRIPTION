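Package: codonusage
Title: Codon Usage Bias Analysis for Compact Eukaryotic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for quantifying synonymous codon usage bias in sets of
    coding sequences: relative synonymous codon usage (RSCU), the codon
    adaptation index (CAI) against a high-expression reference, Wright's
    effective number of codons (ENc) with its expected GC3s curve, positional
    GC composition with the exclusion rules appropriate for parity-rule-2 and
    neutrality analysis, optimal and rare codon identification from CAI
    expression tails, correspondence analysis of gene-by-codon RSCU tables,
    inter-genome clustering of codon usage profiles, and a seeded synthetic
    coding-sequence generator with planted codon preference, mutational
    pressure and expression-tier structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
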