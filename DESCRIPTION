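Package: paralogcnv
Title: Paralog-Aware Copy Number and Recombinant Allele Calling for
    Gene/Pseudogene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls copy-number variants, gene conversions, fusion alleles and
    known small variants at gene/pseudogene loci such as GBA/GBAP1 from
    short-read whole-genome alignments. Combined gene+pseudogene copy number
    is estimated from GC-corrected, normalized depth in the unique
    inter-paralog region with an integer-centered Gaussian mixture model;
    per-site gene copy number at paralog-differentiating sites localizes CNV
    breakpoints; read-backed phasing of the exon 9-11 differentiating sites
    resolves recombinant haplotypes (RecNciI, RecTL, c.1263del+RecTL and
    single GBAP1-like variants) without relying on correct read alignment
    between the paralogs. Also provides the long-read amplicon companion
    procedures (primer-pair allele classification, sentinel-site breakpoint
    bracketing, homopolymer depth-anomaly detection, genotype-quality
    filtering), cohort-level carrier statistics, and a seeded mini-genome
    simulator with paralog-ambiguous read placement that supplies ground
    truth for every caller component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rsamtools,
    IRanges,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
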