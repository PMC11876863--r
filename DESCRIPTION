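Package: translatomics
Title: Multi-Omics Differential Abundance and Translational Regulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for joint analysis of RNA-seq, ribosome
    profiling (Ribo-seq) and TMT-style proteomics data: median-of-ratios
    size-factor normalization, Welch/Benjamini-Hochberg differential
    abundance, translation-efficiency (TE) estimation and regulatory
    classification of differential-TE genes (exclusive, intensified,
    buffered, forwarded), codon occupancy and pause scoring at ribosomal
    A/P sites, preranked gene-set enrichment and hypergeometric
    overrepresentation, and five-group mRNA-protein concordance
    stratification. Ships a synthetic multi-omics generator with planted
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
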