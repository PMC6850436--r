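#' @include categoryCounts.R
NULL

.ratioOrNA <- function(num, den, what) {
  if (den <= 0) {
    warning(sprintf("zero denominator for %s; returning NaN", what))
    return(NaN)
  }
  num / den
}

#' R0: opposing homozygotes over double heterozygotes
#'
#' R0 = (C + G) / E. For parent-offspring pairs R0 is zero (barring
#' mutation and genotyping error, a parent and child can never be
#' homozygous for different alleles), while for unrelated pairs from one
#' homogeneous population its expectation is 1/2 under any
#' allele-frequency spectrum. Values significantly above 1/2 indicate the
#' two genomes are not drawn from the same population.
#'
#' @param x a [CategoryCounts-class] object.
#' @return the statistic; NaN with a warning if the denominator is zero.
#' @examples
#' r0(CategoryCounts(c(0, 0, 1, 0, 8, 0, 1, 0, 0)))
#' @export
setMethod("r0", "CategoryCounts", function(x) {
  .ratioOrNA(oppHom(x), hetHet(x), "R0")
})

#' R1: double heterozygotes over all other polymorphic categories
#'
#' R1 = E / (B + C + D + F + G + H): the double-heterozygote count
#' divided by the count of all sites that are variable within the pair
#' except E itself. For parent-offspring pairs R1 = 1/2 under any
#' allele-frequency spectrum.
#'
#' @param x a [CategoryCounts-class] object.
#' @return the statistic; NaN with a warning if the denominator is zero.
#' @export
setMethod("r1", "CategoryCounts", function(x) {
  .ratioOrNA(hetHet(x), hetHom(x) + oppHom(x), "R1")
})

#' KING-robust kinship estimator
#'
#' kinship = (E - 2(C + G)) / (B + D + H + F + 2E). Within one
#' homogeneous population this estimates the kinship coefficient
#' \eqn{\theta = k_1/4 + k_2/2} without allele frequencies; for pairs
#' whose chromosomes come from different populations it is biased
#' downward (it is unbounded below).
#'
#' @param x a [CategoryCounts-class] object.
#' @return the estimate; NaN with a warning if the denominator is zero.
#' @export
setMethod("kingKinship", "CategoryCounts", function(x) {
  .ratioOrNA(hetHet(x) - 2 * oppHom(x), hetHom(x) + 2 * hetHet(x),
             "KING-robust kinship")
})

#' Fractions of sites IBS0 and IBS2
#'
#' IBS0 = (C + G) / n and IBS2 = (A + E + I) / n where n is the total
#' site count. Unlike R0, R1 and kinship these fractions depend strongly
#' on SNP ascertainment (they count against all sites, variable or not in
#' the pair), and are provided for comparison with IBS-based plots.
#'
#' @param x a [CategoryCounts-class] object.
#' @return named numeric vector c(ibs0 = , ibs2 = ); NaN pair if n = 0.
#' @export
setMethod("ibsFractions", "CategoryCounts", function(x) {
  n <- nSites(x)
  if (n <= 0) {
    warning("zero sites; IBS fractions undefined")
    return(c(ibs0 = NaN, ibs2 = NaN))
  }
  c(ibs0 = oppHom(x) / n, ibs2 = (homSame(x) + hetHet(x)) / n)
})

#' Lee's relatedness test statistic
#'
#' E / (C + G + E): the inverse-oriented companion of R0 with the
#' double-heterozygote count added to the denominator. Its expectation
#' for an unrelated same-population pair is 2/3 under any
#' allele-frequency spectrum; values significantly below 2/3 indicate
#' either relatedness or that the two samples are not from the same
#' homogeneous population.
#'
#' @param x a [CategoryCounts-class] object.
#' @return the statistic; NaN with a warning if the denominator is zero.
#' @export
setMethod("leeStatistic", "CategoryCounts", function(x) {
  .ratioOrNA(hetHet(x), oppHom(x) + hetHet(x), "Lee's statistic")
})

#' All pairwise statistics from a category matrix
#'
#' @param x a [CategoryCounts-class] object.
#' @return a one-row data.frame with columns nSites, r0, r1,
#'   kingKinship, ibs0, ibs2, lee.
#' @examples
#' cc <- countPairMatrix(sample(0:2, 100, TRUE), sample(0:2, 100, TRUE))
#' pairStats(cc)
#' @export
pairStats <- function(x) {
  stopifnot(is(x, "CategoryCounts"))
  ibs <- suppressWarnings(ibsFractions(x))
  data.frame(nSites = nSites(x),
             r0 = suppressWarnings(r0(x)),
             r1 = suppressWarnings(r1(x)),
             kingKinship = suppressWarnings(kingKinship(x)),
             ibs0 = unname(ibs["ibs0"]),
             ibs2 = unname(ibs["ibs2"]),
             lee = suppressWarnings(leeStatistic(x)))
}

## internal: statistics for a matrix of cell-probability rows (no
## warnings, vectorized over rows in a..i order); used by the
## expectation-range scan.
.statsFromCellRows <- function(m) {
  opp <- m[, 3L] + m[, 7L]
  e <- m[, 5L]
  hethom <- m[, 2L] + m[, 4L] + m[, 6L] + m[, 8L]
  data.frame(r0 = opp / e,
             r1 = e / (hethom + opp),
             kinship = (e - 2 * opp) / (hethom + 2 * e))
}

#' IBD coefficients for the standard close relationships
#'
#' Returns (k0, k1, k2) for a named relationship: PO parent-offspring
#' (0, 1, 0), FS full siblings (1/4, 1/2, 1/4), HS half-sibling /
#' avuncular / grandparent-grandchild (1/2, 1/2, 0), C1 first cousins
#' (3/4, 1/4, 0), UR unrelated (1, 0, 0).
#'
#' @param label one of "PO", "FS", "HS", "C1", "UR", or a numeric vector
#'   of three custom k values (then `name` labels it).
#' @param name label to attach when `label` is numeric.
#' @return a [KCoefficients-class] object.
#' @examples
#' thetaFromK(kCoefficients("FS"))
#' @export
kCoefficients <- function(label, name = "custom") {
  if (is.numeric(label))
    return(new("KCoefficients", k = label / sum(label), label = name))
  k <- switch(label,
              PO = c(0, 1, 0),
              FS = c(0.25, 0.5, 0.25),
              HS = c(0.5, 0.5, 0),
              C1 = c(0.75, 0.25, 0),
              UR = c(1, 0, 0),
              stop("unknown relationship label: ", label))
  new("KCoefficients", k = k, label = label)
}

#' @describeIn KCoefficients-class the numeric vector (k0, k1, k2).
#' @param x a KCoefficients object.
#' @export
setMethod("kValues", "KCoefficients", function(x) {
  v <- x@k
  names(v) <- c("k0", "k1", "k2")
  v
})

#' @describeIn KCoefficients-class kinship coefficient
#'   \eqn{\theta = k_1/4 + k_2/2}.
#' @export
setMethod("thetaFromK", "KCoefficients", function(x) {
  x@k[2L] / 4 + x@k[3L] / 2
})

setMethod("show", "KCoefficients", function(object) {
  cat(sprintf("KCoefficients '%s': k0=%.4g k1=%.4g k2=%.4g (theta=%.4g)\n",
              object@label, object@k[1], object@k[2], object@k[3],
              thetaFromK(object)))
})
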