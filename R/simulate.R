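#' @include expectations.R
NULL

## assemble the two genotypes from the four founder haplotype alleles and
## the per-site IBD state, exactly as in the IBD-state-sampling scheme:
## individual 1 is always haplotypes (1,2); individual 2 is (3,4) when
## IBD=0, (1,3) when IBD=1 (haplotype 1 shared) and (1,2) when IBD=2.
.assembleGenotypes <- function(h1, h2, h3, h4, ibd) {
  g1 <- h1 + h2
  g2 <- h3 + h4
  g2[ibd == 1L] <- (h1 + h3)[ibd == 1L]
  g2[ibd == 2L] <- g1[ibd == 2L]
  list(g1 = g1, g2 = g2)
}

#' Simulate genotypes for a pair of relatives
#'
#' Generates a pair of diploid genotype vectors under specified IBD
#' coefficients (k0, k1, k2) by per-site IBD-state sampling. At each
#' site an allele frequency p is drawn from the spectrum, a reference
#' panel of \code{panelSize} chromosomes is drawn Bernoulli(p) whose
#' first four chromosomes are the founder haplotypes, the IBD state is
#' drawn from (k0, k1, k2) independently across sites, and the two
#' genotypes are assembled from the founder alleles according to the IBD
#' state. Sites are rejection-sampled until polymorphic in the
#' reference panel (the simulated "variants" are by construction
#' variable in the simulated sample), and additionally until they pass
#' the minor-allele-count rule when \code{ascertainment} is given;
#' linkage disequilibrium and block structure of IBD are deliberately
#' not modelled.
#'
#' Sites are laid out consecutively on \code{nChromosomes} equal
#' contigs, \code{spacingBp} apart, so chromosome block-jackknife and
#' window subsetting can be exercised.
#'
#' @param relationship a [KCoefficients-class] object or a relationship
#'   label ("PO", "FS", "HS", "C1", "UR").
#' @param nSites number of polymorphic sites to simulate.
#' @param spectrum a [SpectrumModel-class] (default the constant-Ne
#'   1/j spectrum on 40 chromosomes).
#' @param seed integer seed; every stochastic operation in this package
#'   takes an explicit seed and touches no global state beyond R's RNG.
#' @param nChromosomes number of contig labels (default 22).
#' @param ascertainment NULL, or a list with element \code{minMac}
#'   (minimum minor-allele count, exclusive bound is minMac - 1): sites
#'   are then rejection-sampled until the panel minor-allele count is at
#'   least minMac, e.g. \code{list(minMac = 3)} reproduces the
#'   "minor allele count > 2 out of 40 chromosomes" (MAF > 5 percent)
#'   ascertainment rule.
#' @param panelSize reference-panel chromosomes (default 40).
#' @param spacingBp base pairs between consecutive sites (default 50).
#' @param maxRounds rejection-sampling rounds before giving up.
#' @return list with elements \code{g1}, \code{g2} (integer genotypes),
#'   \code{contig}, \code{pos}, \code{p} (drawn frequencies),
#'   \code{panelMinorCount} (minor-allele count among the panel),
#'   \code{ibd} (realized per-site IBD state), \code{alleles} (n x 2
#'   integer matrix of base codes 1..4: ref = allele counted as 0, alt =
#'   counted allele), \code{kRealized} and \code{k}.
#' @examples
#' sim <- simulatePairGenotypes("FS", 5000, seed = 1)
#' pairStats(countPairMatrix(sim$g1, sim$g2))
#' @export
simulatePairGenotypes <- function(relationship, nSites,
                                  spectrum = constantNeSpectrum(),
                                  seed = NULL, nChromosomes = 22L,
                                  ascertainment = NULL, panelSize = 40L,
                                  spacingBp = 50L, maxRounds = 1000L) {
  k <- if (is.character(relationship)) kCoefficients(relationship) else relationship
  stopifnot(is(k, "KCoefficients"), nSites > 0)
  if (!is.null(seed)) set.seed(seed)
  minMac <- if (is.null(ascertainment)) 0L else as.integer(ascertainment$minMac)

  n <- as.integer(nSites)
  p <- numeric(n); h <- matrix(0L, n, 4L); panelMinor <- integer(n)
  todo <- seq_len(n)
  for (round in seq_len(maxRounds)) {
    m <- length(todo)
    if (m == 0L) break
    pp <- sampleFreq(spectrum, m)
    hh <- matrix(stats::rbinom(4L * m, 1L, rep(pp, 4L)), m, 4L)
    rest <- stats::rbinom(m, panelSize - 4L, pp)
    tot <- rowSums(hh) + rest
    minor <- pmin(tot, panelSize - tot)
    keep <- minor >= max(1L, minMac)
    acc <- todo[keep]
    p[acc] <- pp[keep]
    h[acc, ] <- hh[keep, , drop = FALSE]
    panelMinor[acc] <- minor[keep]
    todo <- todo[!keep]
  }
  if (length(todo) > 0L)
    stop("could not satisfy the polymorphism/ascertainment rule after ",
         maxRounds, " rejection rounds; the spectrum is incompatible")

  ibd <- sample(0:2, n, replace = TRUE, prob = k@k)
  g <- .assembleGenotypes(h[, 1L], h[, 2L], h[, 3L], h[, 4L], ibd)

  ## two true bases per site, drawn uniformly without replacement
  refAllele <- sample.int(4L, n, replace = TRUE)
  altAllele <- sample.int(3L, n, replace = TRUE)
  altAllele <- altAllele + (altAllele >= refAllele)

  perChrom <- ceiling(n / nChromosomes)
  idx <- seq_len(n) - 1L
  contig <- paste0("chr", idx %/% perChrom + 1L)
  pos <- as.integer((idx %% perChrom + 1L)) * as.integer(spacingBp)

  kReal <- tabulate(ibd + 1L, nbins = 3L) / n
  names(kReal) <- c("k0", "k1", "k2")
  list(g1 = g$g1, g2 = g$g2, contig = contig, pos = pos, p = p,
       panelMinorCount = panelMinor, ibd = ibd,
       alleles = cbind(ref = refAllele, alt = altAllele),
       kRealized = kReal, k = k)
}

#' Simulate an unrelated pair from two diverged populations
#'
#' Draws, per site, an ancestral allele frequency from \code{spectrum}
#' and two population-specific frequencies from the Balding-Nichols
#' distribution Beta(p (1 - Fst) / Fst, (1 - p)(1 - Fst) / Fst); each
#' individual is an independent Hardy-Weinberg draw within its own
#' population. Such pairs push R0 above its same-population null of 1/2
#' and Lee's statistic below 2/3.
#'
#' @param fst Wright's fixation index between the two populations, in
#'   (0, 1); \code{fst = 0} collapses to a same-population unrelated
#'   pair.
#' @param nSites number of sites.
#' @param spectrum ancestral-frequency [SpectrumModel-class].
#' @param seed integer seed.
#' @param nChromosomes contig labels for jackknife blocking.
#' @return list with \code{g1}, \code{g2}, \code{contig}, \code{pos},
#'   \code{p} (ancestral), \code{p1}, \code{p2} (population
#'   frequencies).
#' @export
simulateCrossPopulationPair <- function(fst, nSites,
                                        spectrum = constantNeSpectrum(),
                                        seed = NULL, nChromosomes = 22L) {
  stopifnot(fst >= 0, fst < 1, nSites > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nSites)
  p <- sampleFreq(spectrum, n)
  if (fst > 0) {
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    p1 <- stats::rbeta(n, a, b)
    p2 <- stats::rbeta(n, a, b)
  } else {
    p1 <- p2 <- p
  }
  g1 <- stats::rbinom(n, 2L, p1)
  g2 <- stats::rbinom(n, 2L, p2)
  perChrom <- ceiling(n / nChromosomes)
  idx <- seq_len(n) - 1L
  list(g1 = g1, g2 = g2,
       contig = paste0("chr", idx %/% perChrom + 1L),
       pos = as.integer(idx %% perChrom + 1L) * 50L,
       p = p, p1 = p1, p2 = p2)
}

#' Minor-allele-count ascertainment mask
#'
#' Boolean mask over sites applying the reference-panel ascertainment
#' rule: keep a site when its minor-allele count in the panel is at
#' least \code{minMac}. The default \code{minMac = 3} reproduces the
#' "minor allele count > 2 out of 40 chromosomes" (MAF > 5 percent)
#' rule.
#'
#' @param panelMinorCount integer vector of per-site minor-allele counts
#'   in the reference panel (as returned by
#'   [simulatePairGenotypes()]).
#' @param minMac minimum minor-allele count; NULL disables the rule
#'   (all-true mask).
#' @return logical vector.
#' @export
ascertainSites <- function(panelMinorCount, minMac = 3L) {
  if (is.null(minMac)) return(rep(TRUE, length(panelMinorCount)))
  panelMinorCount >= minMac
}

#' Random 200-bp window subsetting
#'
#' Emulates reduced-representation (RADseq-like) data: tiles each contig
#' into non-overlapping windows of \code{windowBp} base pairs, samples
#' \code{nWindows} of them uniformly without replacement across the
#' genome, and keeps the sites falling inside sampled windows.
#'
#' @param contig character contig label per site.
#' @param pos integer 1-based position per site.
#' @param nWindows number of windows to sample.
#' @param windowBp window width in base pairs (default 200).
#' @param seed integer seed.
#' @param contigLength named vector of contig lengths in bp; defaults to
#'   the maximum observed position per contig.
#' @return logical mask over sites.
#' @export
subsetWindows <- function(contig, pos, nWindows, windowBp = 200L,
                          seed = NULL, contigLength = NULL) {
  stopifnot(length(contig) == length(pos), nWindows >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(contigLength))
    contigLength <- c(tapply(pos, contig, max))
  tilesPer <- floor(contigLength / windowBp)
  tilesPer[tilesPer < 1] <- 1
  total <- sum(tilesPer)
  if (nWindows > total)
    stop(sprintf("nWindows * windowBp (%d x %d) exceeds the genome span (%d windows available)",
                 as.integer(nWindows), as.integer(windowBp), as.integer(total)))
  chosen <- sort(sample.int(total, nWindows))
  ## map global tile index back to (contig, tile-within-contig)
  contigs <- names(tilesPer)
  offsets <- cumsum(c(0L, tilesPer[-length(tilesPer)]))
  names(offsets) <- contigs
  siteTile <- offsets[contig] + (pos - 1L) %/% windowBp + 1L
  ## sites beyond the last full tile of a contig can never be selected
  inRange <- (pos - 1L) %/% windowBp + 1L <= tilesPer[contig]
  inRange & siteTile %in% chosen
}
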