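Package: PairRelate
Title: Allele-Frequency-Free Pairwise Relatedness from Genotypes and
    Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers close familial relationships between pairs of diploid
    individuals without population allele frequencies or genomic positions.
    Tallies the 3x3 pairwise genotype-category matrix (cells A-I) at
    diallelic sites and computes the ratio statistics R0 and R1 together
    with the KING-robust kinship estimator, which jointly separate
    parent-offspring, full-sibling, second-degree, first-cousin and
    unrelated pairs independently of SNP ascertainment. For low-depth
    sequencing data the category proportions are estimated directly from
    genotype likelihoods by expectation-maximization, either as a
    two-individual site-frequency spectrum (3x3) or over all 100 pairs of
    the ten possible genotypes. Standard errors come from a weighted
    chromosome block-jackknife, and pairs are classified by Euclidean
    distance to simulated reference points or by kinship thresholds. A
    full synthetic-data generator (founder haplotypes drawn from
    configurable allele-frequency spectra, per-site IBD-state sampling,
    Poisson-depth reads with a GATK-style error model, minor-allele-count
    ascertainment and random 200-bp window subsetting) supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PairRelate-package.R'
    'categoryCounts.R'
    'spectrum.R'
    'pairStatistics.R'
    'expectations.R'
    'simulate.R'
    'readsim.R'
    'em.R'
    'jackknife.R'
    'classify.R'
    'io.R'
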