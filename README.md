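# PairRelate

Allele-frequency-free inference of close familial relationships for
pairs of diploid individuals, from genotypes or from low-depth
sequencing genotype likelihoods.

## What problem this solves

Standard relatedness estimators (PLINK-style method-of-moments, most
kinship matrices) need population allele frequencies, and many also need
variant positions or reliably called genotypes. Studies of non-model
organisms, ancient samples, or a handful of low-depth (~4×) genomes have
none of these. PairRelate computes everything from the two target
individuals alone.

At each diallelic site the pair's genotypes (0/1/2 copies of an allele)
fall into one of nine categories, tallied genome-wide into a 3×3 matrix
with cells A–I (rows = individual 1, columns = individual 2). Three
statistics are ratios of its cells:

    R0      = (C + G) / E
    R1      = E / (B + C + D + F + G + H)
    kinship = (E - 2(C + G)) / (B + D + F + H + 2E)     (KING-robust)

where C + G counts opposing homozygotes and E double heterozygotes.
Parent–offspring pairs sit at (R1, R0) = (0.5, 0) and
(R1, kinship) = (0.5, 0.25) under *any* allele-frequency spectrum;
unrelated same-population pairs have R0 = 1/2, kinship = 0 and a Lee
test statistic E/(C+G+E) of 2/3; full siblings, second-degree pairs and
first cousins occupy disjoint regions of the (R1, R0) and (R1, kinship)
planes regardless of the spectrum. That spectrum-independence is what
makes the method robust to SNP ascertainment — unlike IBS0/IBS2-based
plots, which shift wholesale between arrays and sequencing.

For low-depth data the cell counts are estimated by EM directly from
genotype likelihoods (a 3×3 two-individual SFS, or a 10×10
all-base-pairs form that needs no allele information), standard errors
come from a weighted chromosome block-jackknife, and pairs are
classified by nearest simulated reference point in the (R1, R0) plane or
by KING kinship thresholds. A full synthetic-data generator (spectrum-
drawn founder haplotypes, per-site IBD-state sampling, Poisson-depth
reads with a GATK-style error model, MAF ascertainment, random 200-bp
window subsets) backs the validation suite.

## Worked example

Simulate a full-sibling pair (10⁵ SNPs, constant-Ne spectrum), tally the
category matrix, and look at the statistics:

```r
library(PairRelate)
sim <- simulatePairGenotypes("FS", 1e5, seed = 1)
cc  <- countPairMatrix(sim$g1, sim$g2)
cc
#> CategoryCounts (1e+05 sites)
#>    g2
#> g1      0     1    2
#>   0 53881  7321  560
#>   1  7400 15011 3239
#>   2   550  3275 8763
#> opposing hom (C+G) 1110 | het-het (E) 15011 | het-hom 21235 | hom-same 62644

jackknifeStats(perBlockCounts(sim$g1, sim$g2, sim$contig))
#>     statistic   estimate           se nBlocks
#> 1          r0 0.07394577 0.0023122137      22
#> 2          r1 0.67178340 0.0075103830      22
#> 3 kingKinship 0.24954640 0.0020823114      22
#> 4        ibs0 0.01110000 0.0003220663      22
#> 5        ibs2 0.77655000 0.0013651986      22
#> 6         lee 0.93114571 0.0020048166      22
```

Kinship ≈ 1/4 with R0 ≈ 0.07 (well above the parent–offspring value of
0) is the full-sibling signature, and both classifiers agree:

```r
s <- pairStats(cc)
classifyR1R0(s$r1, s$r0)                  # nearest (R1, R0) reference
#> [1] "FS"
classifyKinship(s$kingKinship, s$r0)      # KING kinship bands
#> [1] "FS"
```

The same answer from 4× sequencing likelihoods instead of genotypes:

```r
gl  <- simulatePairGL(sim, meanDepth = 4, errorRate = 0.01,
                      seed = 2, mode = "sfs")$sfs
est <- emSFS2D(gl)
pairStats(emCategoryCounts(est))
#>   nSites         r0        r1 kingKinship       ibs0      ibs2       lee
#> 1  1e+05 0.07340333 0.6791374   0.2510092 0.01108307 0.7776758 0.9316163
```

Real data enter through `readPairVCF()` (GT and PL fields),
`readBeagleGL()` (beagle likelihood text) or `readGL10()` (the
documented 10-genotype table), and `allPairStats()` produces the
per-pair results table for a whole genotype matrix. A thin command-line
front end with `simulate` / `count` / `em` / `classify` /
`expectations` / `make-refs` subcommands is installed at
`inst/scripts/pairrelate`.

The methods vignette (`vignettes/relatedness-inference.Rmd`) documents
the model, the expectation-range construction, EM and jackknife details,
and what the simulator does and does not emulate.

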