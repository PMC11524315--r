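Package: lignoscan
Title: Genome-Wide Cataloguing and Expression Analysis of Monolignol
    Biosynthesis Gene Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide analysis of the eleven monolignol
    (lignin precursor) biosynthesis gene families in plant genomes,
    with particular support for tetraploid willow genomes split into
    At and Bt sub-genomes. Provides family assignment of candidate
    genes by local alignment against reference family members with a
    required-domain gate, detection of duplicated gene pairs by the
    80/80 coverage-identity rule, tandem-duplicate classification and
    chromosomal hotspot scanning, neighbor-joining phylogenies on
    Poisson-corrected pairwise-deletion distances with bootstrap
    support and family-class calling from group monophyly, FPKM
    computation and fold-change/FDR differential-expression calling
    between tall and short genotypes, lignin-content and height
    correlation statistics, and exact IUPAC motif scanning of 2000-bp
    promoter regions. A fully seeded synthetic-study generator emits a
    complete artificial genome, RNA-seq count set, phenotype table and
    promoter set with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, GeneExpression, Transcriptomics,
    SequenceMatching, Annotation
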