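Package: mitoarch
Title: Comparative Architecture Analysis of Yeast Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the organisation of compact, AT-rich
    mitochondrial genomes such as those of budding yeasts. The package
    partitions an annotated genome into genes, introns and intergenic
    sub-elements (free-standing ORFs, replication origins, GC clusters,
    AT spacers and residual sequence), detects GC clusters with a
    two-pass sliding-coverage scan and groups them into consensus
    families, quantifies gene-order conservation (GOC/GOL) between
    genomes, apportions gene-order loss to individual tree branches by
    non-negative least squares, computes double-cut-and-join (DCJ)
    rearrangement distances on syntenic block orders, assigns introns
    across species to homologous loci via flanking-exon conservation,
    and summarises conserved-column identity in multiple sequence
    alignments. A seeded simulator generates annotated circular
    mitochondrial genomes with known architecture and rearrangement
    history for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape,
    pracma,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, ComparativeGenomics, Software
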