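Package: svkit
Title: Sequence-Resolved Structural Variant Annotation and Mechanism Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates sequence-resolved structural variants (SVs) from
    long-read callsets. Classifies insertion alleles into mobile element
    insertions (solo Alu/L1/SVA, partnered and orphan transductions,
    processed pseudogenes), endogenous retrovirus remnants, nuclear
    mitochondrial segments, tandem-repeat expansions and duplications;
    quantifies breakpoint-junction homology and infers SV formation
    mechanisms (end-joining, homology-directed repair, non-allelic
    homologous recombination); aggregates transductions into source-element
    loci with binomial 5'/3' bias tests; builds pseudo-haplotypes for
    pangenome graph augmentation; and screens homology-mediated deletions
    for recurrent, independent origin on distinct haplotype backgrounds.
    Ships a seeded synthetic-data generator producing genomes, callsets and
    haplotype panels with ground-truth labels for every classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
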