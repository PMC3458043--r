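Package: rrsnp
Title: SNP Discovery and Genotyping from Reduced-Representation
    Sequencing of Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for single-nucleotide polymorphism (SNP)
    discovery in polyploid species that lack a reference genome. Builds a
    unigene ("gene space") reference from expressed sequence tag (EST) reads
    by k-mer overlap clustering with sister-EST double linkage and
    majority-vote consensus assembly; maps methylation-sensitive
    reduced-representation short reads onto it with a word-indexed banded
    Smith-Waterman aligner with quality-aware multi-hit resolution; calls
    SNPs and short (1-3 bp) indels with a two-stage, allele-dosage-aware
    depth/ratio/quality filter suited to tetraploid and octoploid genomes;
    calls dominant-marker genotypes and summarises population structure
    (PCA) and per-library diversity. A seeded simulator of polyploid
    genomes, HpaII restriction-anchored read libraries and EST sets with
    complete ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    igraph,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
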