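Package: heritChIP
Title: ChIP-Seq Coverage and Heritable Heterochromatin Analysis with
    Fractional Multimapper Weighting
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for ChIP-seq analysis of nuclear
    RNAi-induced heterochromatin marks (H3K23me3/H3K9me3) in C. elegans-like
    genomes: depth-normalized coverage tracks built from multi-mapped
    alignments weighted 1/(number of alignments) with 500 bp single-end
    read extension, 1 kb-window enrichment and chromosome arm-versus-center
    statistics, mutant-versus-wild-type dependent-gene calling (two-fold,
    replicate-consistent), Fisher's exact gene-set overlap tests, repeat-class
    composition of target genes, and transgenerational enrichment-decay
    analysis. A synthetic-data generator plants genotype- and
    generation-dependent enrichment with known ground truth so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
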