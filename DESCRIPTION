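Package: popscan
Title: Population Genomics and Selection Scans from RNA-Seq Variant Calls
Version: 0.1.0
Authors@R:
    person("Sam", "Reed", email = "sam.reed@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of variants called on RNA-seq
    alignments. Reads multi-sample VCFs, sample sheets, GFF3 annotation and
    marker panels; applies SNP/quality/missingness filters; computes Hudson's
    F_ST (per variant, in windows, and per gene), the population branch
    statistic, nucleotide diversity, Watterson's theta and inbreeding
    coefficients; performs LD pruning and PCA of genotype dosages; estimates
    expressed allele balance at variants of interest from read pileups;
    karyotypes chromosomal inversions in pooled samples from tag SNPs; assigns
    ancestry fractions from ancestry-informative markers; classifies SNPs by
    genomic feature and runs hypergeometric enrichment. A seeded synthetic-data
    generator (Balding-Nichols populations, binomial read sampling, toy
    annotation and marker panels) makes every estimator testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
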