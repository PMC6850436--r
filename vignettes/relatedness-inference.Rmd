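---
title: "Allele-frequency-free relatedness inference with PairRelate"
author: "PairRelate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-frequency-free relatedness inference with PairRelate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PairRelate)
```

# The problem

Most pairwise-relatedness estimators need population allele frequencies,
genomic positions of variants, or accurately called genotypes. None of
these may be available for non-model organisms, ancient samples, or small
low-depth sequencing studies. PairRelate implements a method that needs
none of them: everything is computed from the joint genotype pattern of
the two target individuals alone, site by site, with no ordering
assumptions, and — for sequencing data — from genotype likelihoods rather
than called genotypes.

# The category matrix and the three statistics

At a diallelic site, the genotypes of two diploid individuals (coded 0, 1
or 2 copies of one of the two alleles) fall into one of nine joint
categories, which we arrange in a 3×3 matrix with cells A–I (rows =
individual 1, columns = individual 2, row-major). Genome-wide counts of
these cells — essentially a two-individual site-frequency spectrum — carry
all the information the method uses. The aggregates that matter are the
opposing homozygotes C+G, the double heterozygotes E, the mixed
heterozygote/homozygote cells B+D+F+H, and the identical homozygotes A+I.

From the cell counts PairRelate computes

* **R0** = (C+G)/E,
* **R1** = E/(B+C+D+F+G+H),
* **KING-robust kinship** = (E − 2(C+G)) / (B+D+F+H + 2E),

plus the ascertainment-sensitive companions Fraction IBS0 = (C+G)/N,
Fraction IBS2 = (A+E+I)/N, and Lee's relatedness test statistic
E/(C+G+E).

Three properties make the (R1, R0) and (R1, kinship) planes useful:

1. **Parent–offspring pairs pin R0 at 0 and R1 at 1/2** for *any* allele
   frequency spectrum (a parent and child always share an allele, so
   opposing homozygotes cannot occur, and the expected double-het count
   equals half of the single-het count).
2. **Unrelated same-population pairs pin R0 at 1/2, kinship at 0 and
   Lee's statistic at 2/3** for any spectrum: under Hardy–Weinberg
   independence E[C+G] = 2∑w(p)p²q² and E[E] = 4∑w(p)p²q².
3. For full siblings (k = (¼,½,¼)), second-degree pairs (½,½,0) and
   first cousins (¾,¼,0) the *joint* expectations trace bounded,
   non-overlapping regions as the spectrum varies (see below), so pairs
   can be classified without knowing the spectrum — which is exactly why
   the method tolerates SNP ascertainment: all three statistics are
   ratios over sites variable within the pair.

All statistics are invariant to relabelling the counted allele
(A↔I, B↔H, C↔G, D↔F) and to swapping the individuals (transpose), so no
allele orientation or sample ordering is ever needed. Zero denominators
return `NaN` with a warning rather than an error so that batch analyses
of many pairs keep running.

# Expected values and attainable ranges

For a non-inbred pair, cell probabilities conditional on sharing 0, 1 or
2 alleles identical by descent (IBD) at a site with counted-allele
frequency p are classical: independence (outer product of Hardy–Weinberg
margins) for IBD 0; for IBD 1 the shared allele forces cells
(0,0)=q³, (0,1)=(1,0)=pq², (1,1)=pq, (1,2)=(2,1)=p²q, (2,2)=p³ and
forbids opposing homozygotes; for IBD 2 only the diagonal (HW) is
possible. `ibdConditionalCells()` returns these, `expectedCells()` mixes
them over (k0, k1, k2) and an allele-frequency spectrum.

The expectation of every ratio statistic is a ratio of two functionals
that are *linear* in the spectrum. A ratio of linear functionals over the
simplex of spectra attains its extremes at the vertices, i.e. at
point-mass spectra; `expectationRange()` therefore scans a folded grid
(default 512 points, p from 1/1000 to 1/2) for per-statistic ranges and
samples all two-point mixtures of a thinned grid to trace the attainable
joint regions. This numerical construction reproduces every analytic
anchor (PO collapses to the single point (0.5, 0) / (0.5, 0.25); the UR
region is the vertical line R0 = 0.5, kinship = 0) and the test suite
verifies that the FS/HS/C1/UR regions do not overlap and that the PO
point touches only the FS region (its p → 0 limit).

Whether the original derivation of these ranges used point-mass extremes
or a functional argument is not documented anywhere we can check; the
grid construction is justified by the linearity argument above and is
verifiable by brute force, which is why we chose it.

# Estimation from genotype likelihoods

At ~4× depth genotypes cannot be called reliably, so the category counts
are estimated by maximum likelihood directly from genotype likelihoods,
treating the nine (or hundred, see below) joint categories as mixture
components: the likelihood of a site is ∑ π(g1,g2)·GL1(g1)·GL2(g2), and
EM alternates the per-site posterior over components with its mean.
Two input forms are supported:

* **SFS form** (`emSFS2D()`): three likelihoods per individual per site
  for 0/1/2 copies of the site's alternate allele, given a designated
  known allele — the classical two-individual SFS estimation. The known
  allele comes from input metadata (the simulator records truth alleles;
  for real data the user supplies, e.g., a consensus or reference
  allele). Deriving it from a high-depth consensus of BAM files is
  outside this package's scope, which consumes likelihoods, not
  alignments.
* **IBS form** (`emIBS()`): ten likelihoods per individual per site, one
  per unordered base pair, requiring no knowledge of the alleles at all.
  The 100 estimated joint proportions are collapsed to the A–I
  aggregates by `collapseIBS()`; joint genotypes whose allele union
  exceeds two bases (e.g. AC/AG) cannot belong to a diallelic site and
  their (tiny) mass is reported separately and discarded.

Numerical choices: likelihood vectors are scale-free and renormalized to
a per-site maximum of one; log-likelihoods are accumulated in log space;
initialization is uniform; iteration stops when the log-likelihood gain
*and* movement fall below `tol`. The default is `tol = 1e-9` with
`maxIter = 5000`: mixture weights whose true value lies on the simplex
boundary — the opposing-homozygote cell of a parent–offspring pair is the
canonical case — converge sublinearly, and stopping at a looser 1e-6
leaves that cell visibly inflated (R0 ≈ 0.002 instead of the converged
≈ 0.001 at 10⁶ sites and 4× depth). EM acceleration schemes are out of
scope.

`chunkedEstimate()` analyses each chromosome separately (one likelihood
pass per EM iteration, so memory stays modest) and pools the expected
counts. Per-chromosome analysis of *small* data sets inflates the
estimated number of opposing-homozygote sites — each small chunk pays the
boundary-elevation cost separately — so the function warns when chunks
are small, and the recommended pattern (used throughout the tests) is:
per-chromosome estimates feed the block jackknife, while the reported
point estimate comes from a single run over all sites.

Hard-call genotype likelihoods (one-hot vectors) make both EMs reproduce
`countPairMatrix()` cell-exactly, which the tests assert, and the
log-likelihood trace is checked to be non-decreasing on every fixture.

As a negative control, `callGenotypesNaive()` picks the per-site argmax
genotype. At 4× depth heterozygotes are systematically undercalled, so
kinship estimates from called genotypes are biased far downward for
related pairs (PO kinship ≈ 0.02 instead of 0.25 in the test
conditions) — the reason the likelihood-based route exists.

# Uncertainty

Sites are not independent within a genome (linkage disequilibrium and
shared IBD segments), so naive per-site standard errors are wrong.
`blockJackknife()` implements the weighted delete-one-block jackknife
(the delete-m_j estimator of Busing, Meijer & van der Leeden 1999) with
blocks = chromosomes: leave-one-out estimates are computed by
re-aggregating the remaining blocks' *counts* and re-evaluating the
statistic — never by averaging per-block statistics — with block weights
proportional to site counts. When blocks are equal-sized this reduces
exactly to the classical delete-one jackknife (asserted in the tests).
Intervals are reported as ±2 SE. For inputs without genomic metadata,
`makeBlocks()` assigns contiguous pseudo-chromosomes; this is weaker
(correlation crosses block boundaries) and is documented as such. A
coverage experiment in the test suite (200 unrelated-pair replicates, 22
equal blocks) checks that the ±2 SE interval for R0 covers 1/2 between
90% and 99% of the time.

# Classification

Two schemes are provided:

* `classifyR1R0()`: nearest reference point in the (R1, R0) plane by
  Euclidean distance. The shipped reference points (one per
  relationship) were generated by the package's own simulator under the
  constant-Ne spectrum with seed 42 and 5×10⁵ sites; the file records
  the provenance and `makeReferencePoints()` regenerates it. Exact ties
  break toward the less-related label — the conservative choice, since
  calling a related pair unrelated prompts no action while the reverse
  does; the original rule's tie-breaking is not documented anywhere, so
  this is a package decision, stated rather than inferred.
* `classifyKinship()`: kinship bands at 2^(−3/2), 2^(−5/2), 2^(−7/2),
  2^(−9/2) — the standard KING criteria — extended downward with a
  2^(−13/2) floor separating "unknown/distantly related" (4th–5th
  degree) from unrelated. The first-degree band is split into PO vs FS
  by R0 < 0.02 (PO expects R0 = 0 exactly, FS well above). Kinship above
  2^(−3/2) flags duplicates/monozygotic twins.

On simulated PO/FS/HS/UR pairs the two schemes agree and both recover
the true label, from genotypes and from 4× likelihoods (test suite).

# The synthetic-data generator

`simulatePairGenotypes()` is the package's fixture factory and defines
its study conditions:

* Per site, an allele frequency is drawn from a `SpectrumModel`; the
  default is the constant-population-size expectation (weights ∝ 1/j on
  frequencies j/40, j = 1..39), matching the 40-chromosome reference
  panel used for ascertainment. "Growth" and "decline" demographies are
  tilted 1/j^1.5 and 1/j^0.5 spectra — qualitative stand-ins for
  coalescent-simulated population-size changes, chosen because the
  statistics depend on the spectrum only weakly (that insensitivity is
  itself what the tests demonstrate). Spectrum sampling replaces a
  coalescent simulator to keep the package dependency-light and
  seed-exact; externally simulated four-haplotype panels can be fed in
  through the genotype route if coalescent parity is wanted.
* A panel of 40 chromosomes is drawn Bernoulli(p); its first four are
  the founder haplotypes. Sites are rejection-sampled until polymorphic
  in the panel (and until the minor-allele count passes the
  ascertainment rule if one is configured). Conditioning on panel
  polymorphism tilts the realized spectrum and the A/I cells together in
  a way that cancels exactly in R0, R1, kinship and Lee — so the
  analytic anchors survive — while IBS0/IBS2 are on the "variable in
  this sample" scale, as they always are in practice.
* The IBD state at each site is drawn independently from (k0, k1, k2)
  and the two genotypes are assembled from founder alleles (individual
  1 = haplotypes 1+2; IBD 0 → 3+4, IBD 1 → 1+3, IBD 2 → 1+2).
  Linkage disequilibrium and the block structure of real IBD segments
  are deliberately **not** modelled; chromosome labels are contiguous
  site blocks that exist to exercise the jackknife machinery, not to
  carry correlation. Consequently the simulator validates the
  *estimators* and the classification geometry, not the jackknife's
  ability to absorb LD — on real data the chromosome jackknife is wider
  than the site-independent one, and passing tests here do not quantify
  that.
* `simulateReadsGL()` draws Poisson(λ) reads per site (default λ = 4,
  the "low-depth" regime of interest), each read sampling one of the
  genotype's two alleles and miscalled with probability ε = 0.01 (Q20)
  to a uniform other base; likelihoods follow the independent-error
  model GL(g) = ∏ reads [½P(b|a₁) + ½P(b|a₂)], P(b|a) = 1−ε or ε/3.
  Base-quality variation, mapping error and reference bias are not
  emulated, so real low-depth data will be somewhat noisier than these
  fixtures.
* `simulateCrossPopulationPair()` draws population-specific frequencies
  from a Balding–Nichols Beta distribution at a given Fst to produce
  unrelated pairs whose genomes come from different populations — the
  case the R0 > 1/2 / Lee < 2/3 diagnostics detect.
* `ascertainSites()` applies the "minor allele count > 2 out of 40"
  (MAF > 5%) panel rule; `subsetWindows()` samples non-overlapping
  200-bp windows to emulate reduced-representation (RADseq-like) site
  sets.

# Problem sizes and test design

The validation suite simulates 10⁶ sites for the headline checks (PO
anchor, cross-population signal, 4× EM recovery with 22-chromosome
jackknife, window subsetting at 50k/10k windows), 2×10⁶ for the
unrelated-null checks across the three demography spectra, and 200
replicates of 22×1000 sites for jackknife calibration — sizes chosen so
Monte-Carlo error sits well inside the assertion tolerances while the
whole suite runs in minutes. The 100-component IBS EM is validated at
10⁴–10⁵ sites (its site × 100 likelihood matrix is the memory-heavy
object; per-chromosome chunking is the intended route for larger data).

# Limitations

* Individuals are assumed non-inbred and from one homogeneous
  population; admixture and inbreeding bias the statistics in
  data-dependent directions and no correction is attempted (comparing
  heterozygosities across individuals is a practical warning signal for
  inbreeding; R0 ≫ 1/2 flags mixed ancestry).
* First cousins versus more distant relationships is intrinsically hard:
  biological variance in realized IBD between same-pedigree pairs
  overlaps categories, and no per-pair statistic can resolve it.
* Classification resolution stops at first cousins; no pedigree
  reconstruction.
* BAM/pileup handling, read filters and mappability masks are out of
  scope: the package consumes genotypes or genotype likelihoods (VCF
  GT/PL, beagle text, or its documented 10-genotype table).
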