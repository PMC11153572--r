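Package: yinyangscan
Title: Detection and Characterisation of Exclusive Yin-Yang Haplotype Pairs
    from Unphased Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects exclusive yin-yang haplotype pairs - chains of common
    biallelic SNPs in complete or near-complete linkage disequilibrium in
    which one haplotype carries only reference alleles and the other only
    alternate alleles - from unphased multi-sample genotype data. Provides
    a fast average-genotype-distance scan, greedy chain assembly with
    region and callability exclusions, a repeat-artifact filter based on
    genotype counts, read depth and allele balance, per-haplotype metrics
    (recombination-map genetic length, Wright's fixation index across
    superpopulations with matched control SNPs, singleton/doubleton and
    heterozygosity background statistics), classification of haplotype
    ancestry against chimpanzee and Neanderthal outgroup alleles, and gene
    and GWAS-catalogue annotation. Includes a seeded synthetic-cohort
    generator with planted haplotype pairs, repeat-artifact loci and
    background variation so that the full pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
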