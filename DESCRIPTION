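Package: selscape
Title: Landscape Genomics Selection Scans and Genotype-Environment Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-genomics analysis of structured populations:
    genotype-level quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test) and linkage-disequilibrium pruning; windowed
    Weir-Cockerham FST and cross-population extended haplotype homozygosity
    (XP-EHH) selection scans with empirical rank significance and cross-method
    overlap; genotype PCA; partial redundancy analysis (RDA) conditioned on
    geography for genotype-environment and genotype-phenotype association with
    loading-outlier candidate detection; window-to-gene interval mapping and
    hypergeometric gene-set enrichment. Includes a seeded simulator of
    hierarchically structured populations (Balding-Nichols differentiation,
    founder-mosaic haplotypes, injected selective sweeps, environmental clines
    and polygenic traits) emulating a gradient-by-agroecology sampling design,
    used as the tested substrate for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
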