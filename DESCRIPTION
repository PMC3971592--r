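Package: mitorate
Title: Comparative Substitution-Rate Analysis of Mitochondrial Genome Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-mitogenome comparative rate analysis for closely related
    taxa (conspecific and congeneric pairs): region-partitioned uncorrected
    distances for protein-coding genes (split into first-plus-second and
    third codon positions), tRNAs, rRNAs and noncoding regions; pairwise
    maximum-likelihood dN/dS under a Goldman-Yang codon model with F3x4
    frequencies and the ascidian mitochondrial genetic code, with a
    Nei-Gojobori counting estimator as an independent cross-check;
    substitution-saturation assessment; an intraspecies-versus-congeneric
    dN-gap statistic that flags candidate ongoing-speciation pairs;
    cloverleaf-aware tRNA substitution analysis (compensatory versus
    mispairing stem changes, tRNA-like anomaly screening); and comparison of
    noncoding-region architecture across conspecific genomes (homopolymer
    runs, true indels versus start/stop-codon boundary shifts). A seeded
    simulator generates annotated mitogenome pairs and cohorts with the same
    statistical structure, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
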