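Package: cpcub
Title: Codon Usage Bias Analysis for Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synonymous codon usage in plastid genomes:
    quadripartite (LSC/SSC/IR) structure detection on circular genomes,
    coding-sequence extraction under standard filters, positional GC content,
    relative synonymous codon usage (RSCU), the effective number of codons
    (ENC, observed and expected), the codon adaptation index (CAI), parity
    rule 2 (PR2) coordinates, neutrality and ENC-plot diagnostics, and
    optimal-codon determination from delta-RSCU between high- and
    low-expression gene libraries. Includes seeded simulators for coding
    sequences with controllable mutational and selective codon-usage
    structure and for circular genomes with planted inverted repeats, so
    every stage of the pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
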