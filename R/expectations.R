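#' @include pairStatistics.R spectrum.R
NULL

#' Hardy-Weinberg genotype probabilities
#'
#' @param p frequency of the counted allele.
#' @return numeric vector (P(0), P(1), P(2)) = (q^2, 2pq, p^2).
#' @export
hwProbs <- function(p) {
  q <- 1 - p
  c(q * q, 2 * p * q, p * p)
}

#' Genotype-pair probabilities conditional on IBD state
#'
#' For a diallelic site with counted-allele frequency p and a non-inbred
#' pair of individuals, returns the three 3x3 matrices of joint genotype
#' probabilities conditional on the pair sharing 0, 1 or 2 alleles IBD:
#' \itemize{
#'  \item IBD 0: the two genotypes are independent Hardy-Weinberg draws,
#'    cell (g1, g2) = HW(g1) HW(g2).
#'  \item IBD 1: one allele is shared; with q = 1 - p the cells are
#'    (0,0)=q^3, (0,1)=(1,0)=pq^2, (1,1)=pq, (1,2)=(2,1)=p^2 q,
#'    (2,2)=p^3 and the opposing-homozygote cells are 0.
#'  \item IBD 2: both alleles shared, diagonal = HW, off-diagonal 0.
#' }
#'
#' @param p allele frequency strictly inside (0, 1).
#' @return list of three 3x3 matrices named ibd0, ibd1, ibd2, each
#'   summing to one.
#' @examples
#' ibdConditionalCells(0.5)$ibd1
#' @export
ibdConditionalCells <- function(p) {
  if (length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("'p' must be a single frequency strictly inside (0, 1)")
  q <- 1 - p
  hw <- hwProbs(p)
  m0 <- outer(hw, hw)
  m1 <- matrix(c(q^3,     p * q^2, 0,
                 p * q^2, p * q,   p^2 * q,
                 0,       p^2 * q, p^3),
               3L, 3L, byrow = TRUE)
  m2 <- diag(hw)
  dn <- list(g1 = 0:2, g2 = 0:2)
  dimnames(m0) <- dimnames(m1) <- dimnames(m2) <- dn
  list(ibd0 = m0, ibd1 = m1, ibd2 = m2)
}

## internal: rows of expected cell probabilities (a..i order) for each
## grid frequency of a spectrum, for fixed (k0,k1,k2).
.cellRowsByFreq <- function(k, p) {
  q <- 1 - p
  hw0 <- q * q; hw1 <- 2 * p * q; hw2 <- p * p
  k0 <- k[1L]; k1 <- k[2L]; k2 <- k[3L]
  cbind(a = k0 * hw0 * hw0 + k1 * q^3 + k2 * hw0,
        b = k0 * hw0 * hw1 + k1 * p * q^2,
        c = k0 * hw0 * hw2,
        d = k0 * hw1 * hw0 + k1 * p * q^2,
        e = k0 * hw1 * hw1 + k1 * p * q + k2 * hw1,
        f = k0 * hw1 * hw2 + k1 * p^2 * q,
        g = k0 * hw2 * hw0,
        h = k0 * hw2 * hw1 + k1 * p^2 * q,
        i = k0 * hw2 * hw2 + k1 * p^3 + k2 * hw2)
}

#' Expected category probabilities for a relationship and spectrum
#'
#' Mixes the IBD-conditional genotype-pair probabilities over the IBD
#' coefficients (k0, k1, k2) and averages over the allele-frequency
#' spectrum: cells = sum_p w(p) [k0 M0(p) + k1 M1(p) + k2 M2(p)].
#'
#' @param k a [KCoefficients-class] object (or relationship label).
#' @param spectrum a [SpectrumModel-class].
#' @return a [CategoryCounts-class] of probabilities (cells sum to 1).
#' @examples
#' pairStats(expectedCells(kCoefficients("FS"), pointSpectrum(0.5)))
#' @export
expectedCells <- function(k, spectrum) {
  if (is.character(k)) k <- kCoefficients(k)
  stopifnot(is(k, "KCoefficients"), is(spectrum, "SpectrumModel"))
  rows <- .cellRowsByFreq(k@k, spectrum@p)
  cellProbs <- colSums(rows * spectrum@w)
  CategoryCounts(cellProbs)
}

#' Attainable expectation ranges over all allele-frequency spectra
#'
#' For a fixed relationship, scans a folded frequency grid for the range
#' of the expected R0, R1 and KING-robust kinship statistics over all
#' possible allele-frequency spectra. Each expected statistic is a ratio
#' of two spectrum-linear functionals, so its extremes over arbitrary
#' spectra are attained on point-mass spectra (the grid scan); the
#' attainable region in the joint (R1, R0) and (R1, kinship) planes is
#' sampled over single frequencies plus all two-point mixtures of a
#' sub-grid.
#'
#' @param k a [KCoefficients-class] object (or relationship label).
#' @param pGrid frequency grid; default 512 points in [1/1000, 1/2].
#' @param nMixGrid number of grid points kept for the two-point-mixture
#'   scan of the joint region.
#' @param mixWeights mixture weights used in the two-point scan.
#' @return an [ExpectationRange-class] object.
#' @examples
#' expectationRange("PO")
#' @export
expectationRange <- function(k,
                             pGrid = seq(0.001, 0.5, length.out = 512L),
                             nMixGrid = 40L,
                             mixWeights = seq(0.05, 0.95, by = 0.05)) {
  if (is.character(k)) k <- kCoefficients(k)
  stopifnot(is(k, "KCoefficients"))
  if (length(pGrid) == 0L) stop("empty frequency grid")
  if (any(pGrid <= 0 | pGrid >= 1)) stop("grid must lie inside (0, 1)")

  rows <- .cellRowsByFreq(k@k, pGrid)           # point-mass expectations
  pointStats <- .statsFromCellRows(rows)

  ## two-point mixtures on a thinned grid trace the joint region
  idx <- unique(round(seq(1L, length(pGrid), length.out = min(nMixGrid, length(pGrid)))))
  pairsIdx <- utils::combn(idx, 2L)
  mixRows <- do.call(rbind, lapply(mixWeights, function(t) {
    t * rows[pairsIdx[1L, ], , drop = FALSE] +
      (1 - t) * rows[pairsIdx[2L, ], , drop = FALSE]
  }))
  boundary <- rbind(pointStats, .statsFromCellRows(mixRows))

  ranges <- data.frame(
    statistic = c("r0", "r1", "kinship"),
    min = c(min(pointStats$r0), min(pointStats$r1), min(pointStats$kinship)),
    max = c(max(pointStats$r0), max(pointStats$r1), max(pointStats$kinship)))
  new("ExpectationRange", relationship = k@label, ranges = ranges,
      boundary = boundary[, c("r1", "r0", "kinship")])
}

setMethod("show", "ExpectationRange", function(object) {
  cat(sprintf("ExpectationRange for %s\n", object@relationship))
  print(object@ranges, row.names = FALSE)
})

#' Expectation-range table for several relationships
#'
#' @param labels relationship labels.
#' @param ... passed to [expectationRange()].
#' @return data.frame with one row per relationship and statistic.
#' @export
expectationRangeTable <- function(labels = c("PO", "FS", "HS", "C1", "UR"),
                                  ...) {
  do.call(rbind, lapply(labels, function(lb) {
    er <- expectationRange(lb, ...)
    cbind(relationship = lb, er@ranges)
  }))
}
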