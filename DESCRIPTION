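Package: nemadiv
Title: Comparative Genomics of Nematode Genome Pairs: Neutral Divergence
    Dating, LTR Retrotransposon Classification and Synteny
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of closely related nematode
    genome assemblies. Implements Nei-Gojobori (1986) counting of
    synonymous and nonsynonymous substitutions with Jukes-Cantor
    correction, Wright's effective number of codons (Nc) and an
    Nc-regression calibration of synonymous divergence, and the neutral
    divergence clock T = dS/mu. Also provides assembly statistics and
    residual-haplotype (haplotig) filtering, merging and confidence
    classification of LTR retrotransposon candidates from multiple
    detectors, collinear synteny-block chaining with arm/centre and
    X-versus-autosome substitution-rate contrasts, and a fully seeded
    synthetic genome-pair simulator supplying ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ComparativeGenomics, Genetics, Software, SequenceMatching,
    WholeGenome
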