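Package: LDannotate
Title: Functional Annotation of GWAS Risk Loci from Phased Haplotype Panels
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-GWAS functional annotation of disease risk loci. Expands
    GWAS index SNPs to correlated variants by computing linkage
    disequilibrium (r-squared, D, D-prime) directly from phased haplotype
    panels in VCF, stratifies correlated SNPs into LD classes, classifies
    high-LD SNPs into exon, transcription-start-site and enhancer
    categories by coincidence with chromatin biofeature tracks, scores
    allele-specific transcription-factor motif disruption with position
    weight matrix log-odds and exact match p-values, projects exonic SNPs
    to codon changes and haplotype protein isoforms, and joins external
    eQTL evidence. Ships a synthetic-data generator that plants two-locus
    LD at target r-squared, chromatin peaks, and motif-disrupting SNPs
    with a machine-readable ground-truth manifest, so the whole pipeline
    is testable without population-scale downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, SNP, FunctionalGenomics, Annotation,
    LinkageDisequilibrium, MotifAnnotation
RoxygenNote: 7.3.3
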