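Package: cdgScan
Title: Genome-Wide Census of c-di-GMP Signaling Components in Rhizobia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Motif-based prediction of functional diguanylate cyclases (GGDEF
    domains), phosphodiesterases (EAL domains) and PilZ-type c-di-GMP
    receptors in bacterial proteomes, using spacing-constrained activity
    motifs with explicit essential-residue diagnostics and allosteric I-site
    detection. Builds per-genome censuses of signaling components from
    annotated genomes (GenBank or GFF3 + FASTA) and external or heuristic
    domain-hit tables, computes upstream-intergenic GC-content statistics
    against genome and replicon baselines, and summarizes gene expression as
    RPKM with two-way ANOVA variance partitioning and Bonferroni pairwise
    comparisons. Ships a synthetic-data generator (proteins with planted
    motifs, multi-replicon annotated genomes, negative-binomial count tables)
    so every stage of the pipeline is testable offline.
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
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, Genetics, GeneExpression, Bacteria
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cdgScan-package.R'
    'motif-engine.R'
    'domain-locator.R'
    'genome-census.R'
    'promoter-gc.R'
    'expression.R'
    'synthetic-data.R'
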