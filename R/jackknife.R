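#' @include em.R
NULL

#' Per-contig category counts from genotype data
#'
#' Tallies a [CategoryCounts-class] per contig, the blocking unit for
#' the chromosome jackknife.
#'
#' @param g1,g2 genotype vectors (0/1/2/NA).
#' @param contig contig label per site.
#' @return named list of [CategoryCounts-class], in order of first
#'   appearance of each contig.
#' @export
perBlockCounts <- function(g1, g2, contig) {
  stopifnot(length(g1) == length(g2), length(contig) == length(g1))
  contigs <- unique(contig)
  out <- lapply(contigs, function(ct) {
    keep <- contig == ct
    countPairMatrix(g1[keep], g2[keep])
  })
  names(out) <- contigs
  out
}

#' Contiguous-site fallback blocks
#'
#' Assigns contiguous blocks of sites to pseudo-contigs for inputs
#' without genomic metadata. Weaker than true chromosome blocks (shared
#' IBD segments and LD can span block boundaries), but allows a
#' jackknife when no positional information exists.
#'
#' @param n number of sites.
#' @param nBlocks number of blocks (default 22).
#' @return character vector of block labels.
#' @export
makeBlocks <- function(n, nBlocks = 22L) {
  per <- ceiling(n / nBlocks)
  paste0("block", (seq_len(n) - 1L) %/% per + 1L)
}

#' Weighted block-jackknife for statistics of category counts
#'
#' Delete-one-block (chromosome) jackknife with unequal block sizes,
#' using the weighted (delete-m_j) variance estimator of Busing, Meijer
#' and van der Leeden (1999). Leave-one-out estimates are obtained by
#' re-aggregating the remaining blocks' counts and re-evaluating the
#' statistic on the pooled counts - never by averaging per-block
#' statistics. With h_j = n / n_j (n_j = sites in block j) the
#' pseudovalues are \eqn{\tilde\theta_j = h_j \hat\theta - (h_j - 1)
#' \hat\theta_{(-j)}}, the bias-corrected estimate is
#' \eqn{g \hat\theta - \sum_j (1 - n_j/n) \hat\theta_{(-j)}} and the
#' variance is \eqn{(1/g) \sum_j (\tilde\theta_j - \hat\theta_J)^2 /
#' (h_j - 1)}. When all blocks have equal size this reduces exactly to
#' the classical delete-one jackknife. Intervals in this package are
#' reported as estimate +/- 2 SE.
#'
#' @param blocks list of per-block [CategoryCounts-class] objects (from
#'   [perBlockCounts()] or [chunkedEstimate()]).
#' @param statFun function mapping a [CategoryCounts-class] to a named
#'   numeric vector of statistics; defaults to the six standard pairwise
#'   statistics.
#' @return named list of [JackknifeResult-class], one per statistic.
#'   With fewer than two blocks the SE is NaN (with a warning); a block
#'   whose removal makes a statistic undefined has its pseudovalue
#'   dropped with a warning.
#' @examples
#' sim <- simulatePairGenotypes("HS", 20000, seed = 5)
#' bl <- perBlockCounts(sim$g1, sim$g2, sim$contig)
#' blockJackknife(bl)[["r0"]]
#' @export
blockJackknife <- function(blocks, statFun = NULL) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  if (is.null(statFun)) {
    statFun <- function(cc) {
      s <- pairStats(cc)
      c(r0 = s$r0, r1 = s$r1, kingKinship = s$kingKinship,
        ibs0 = s$ibs0, ibs2 = s$ibs2, lee = s$lee)
    }
  }
  g <- length(blocks)
  pooled <- Reduce(`+`, blocks)
  theta <- statFun(pooled)
  nj <- vapply(blocks, nSites, numeric(1))
  n <- sum(nj)

  if (g < 2L) {
    warning("fewer than 2 blocks: jackknife SE undefined")
    return(.jkResults(theta, NaN, 1L, matrix(NA_real_, 1L, length(theta)), nj))
  }

  loo <- vapply(seq_len(g), function(j) {
    suppressWarnings(statFun(pooled - blocks[[j]]))
  }, numeric(length(theta)))
  loo <- matrix(loo, nrow = length(theta))  # stats x blocks
  rownames(loo) <- names(theta)

  h <- n / nj
  se <- vapply(seq_along(theta), function(s) {
    lo <- loo[s, ]
    keep <- is.finite(lo)
    if (!all(keep))
      warning(sprintf("dropped %d pseudovalue(s) with undefined '%s'",
                      sum(!keep), names(theta)[s]))
    gk <- sum(keep)
    if (gk < 2L || !is.finite(theta[s])) return(NaN)
    hj <- h[keep]
    thetaJ <- gk * theta[s] - sum((1 - nj[keep] / n) * lo[keep])
    pseudo <- hj * theta[s] - (hj - 1) * lo[keep]
    sqrt(sum((pseudo - thetaJ)^2 / (hj - 1)) / gk)
  }, numeric(1))

  .jkResults(theta, se, g, t(loo), nj)
}

.jkResults <- function(theta, se, g, loo, nj) {
  se <- rep_len(se, length(theta))
  out <- lapply(seq_along(theta), function(s) {
    new("JackknifeResult", statistic = names(theta)[s],
        estimate = unname(theta[s]), se = unname(se[s]),
        nBlocks = as.integer(g), loo = unname(loo[, s]),
        weights = unname(nj))
  })
  names(out) <- names(theta)
  out
}

#' @describeIn JackknifeResult-class the jackknife standard error.
#' @param x a JackknifeResult.
#' @export
setMethod("seEstimate", "JackknifeResult", function(x) x@se)

setMethod("show", "JackknifeResult", function(object) {
  cat(sprintf("%s = %.6g +/- %.3g (2 SE; %d blocks)\n", object@statistic,
              object@estimate, 2 * object@se, object@nBlocks))
})

#' Pairwise statistics with jackknife standard errors
#'
#' Convenience wrapper: pooled statistics plus the weighted chromosome
#' block-jackknife SE for each, as one tidy row-per-statistic table.
#'
#' @param blocks list of per-block [CategoryCounts-class] objects.
#' @return data.frame with columns statistic, estimate, se, nBlocks.
#' @export
jackknifeStats <- function(blocks) {
  jk <- blockJackknife(blocks)
  data.frame(statistic = vapply(jk, function(x) x@statistic, character(1)),
             estimate = vapply(jk, function(x) x@estimate, numeric(1)),
             se = vapply(jk, function(x) x@se, numeric(1)),
             nBlocks = vapply(jk, function(x) x@nBlocks, integer(1)),
             row.names = NULL)
}
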