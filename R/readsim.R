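#' @include simulate.R
NULL

.BASES <- c("A", "C", "G", "T")

## the ten unordered base pairs, in lexicographic order
.GENO10 <- cbind(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L),
                 c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 3L, 4L, 4L))

#' Names of the ten unordered genotypes
#'
#' @return character vector "AA", "AC", ..., "TT" in the column order
#'   used by all 10-genotype likelihood matrices in this package.
#' @export
genotype10Names <- function() {
  paste0(.BASES[.GENO10[, 1L]], .BASES[.GENO10[, 2L]])
}

## lookup: base pair (i, j) -> column index in the 10-genotype order
.pairIndex <- local({
  m <- matrix(NA_integer_, 4L, 4L)
  for (k in 1:10) {
    m[.GENO10[k, 1L], .GENO10[k, 2L]] <- k
    m[.GENO10[k, 2L], .GENO10[k, 1L]] <- k
  }
  m
})

## P(observed base | true allele) under the independent-error model
.baseGivenAllele <- function(errorRate) {
  m <- matrix(errorRate / 3, 4L, 4L)
  diag(m) <- 1 - errorRate
  m
}

## 10 x 4 matrix of log P(base | genotype): each read is drawn from one
## of the genotype's two alleles with probability 1/2 each.
.logBaseGivenGeno <- function(errorRate) {
  pb <- .baseGivenAllele(errorRate)
  log(0.5 * pb[.GENO10[, 1L], ] + 0.5 * pb[.GENO10[, 2L], ])
}

## rowwise max of a numeric matrix without apply()
.rowMax <- function(m) {
  r <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) r <- pmax(r, m[, j])
  r
}

## distribute per-site error reads uniformly over the three non-origin
## bases; returns n x 3 integer matrix
.splitErrors <- function(nErr) {
  e1 <- stats::rbinom(length(nErr), nErr, 1 / 3)
  e2 <- stats::rbinom(length(nErr), nErr - e1, 1 / 2)
  cbind(e1, e2, nErr - e1 - e2)
}

## the three bases other than 'a' (codes 1..4), in increasing order
.otherBases <- function(a) {
  cbind(ifelse(a == 1L, 2L, 1L),
        ifelse(a <= 2L, 3L, 2L),
        ifelse(a == 4L, 3L, 4L))
}

#' Simulate sequencing reads and genotype likelihoods for one individual
#'
#' Per site, draws a Poisson(\code{meanDepth}) number of reads; each
#' read samples one of the two alleles of the true genotype uniformly
#' and is miscalled with probability \code{errorRate} to a uniformly
#' chosen different base. Genotype likelihoods follow the independent-
#' error model GL(g) = prod over reads of [P(base | allele1)/2 +
#' P(base | allele2)/2] with P(base | allele) = 1 - e when they match
#' and e/3 otherwise, computed for all ten unordered base pairs and for
#' the three diallelic genotypes given the site's designated alleles.
#' Likelihoods are normalized per site to maximum one (accumulated in
#' log space).
#'
#' @param genotypes integer vector, 0/1/2 copies of the site's alternate
#'   allele.
#' @param alleles n x 2 integer matrix of base codes 1..4 (columns ref,
#'   alt), as produced by [simulatePairGenotypes()].
#' @param meanDepth mean sequencing depth (Poisson rate, default 4).
#' @param errorRate per-base error probability (default 0.01, i.e. Q20).
#' @param seed integer seed.
#' @return list with \code{gl10} (n x 10), \code{gl3} (n x 3, genotypes
#'   = copies of the alternate allele), \code{depth}, and
#'   \code{baseCounts} (n x 4 read tallies).
#' @export
simulateReadsGL <- function(genotypes, alleles, meanDepth = 4,
                            errorRate = 0.01, seed = NULL) {
  if (meanDepth <= 0) stop("'meanDepth' must be positive")
  stopifnot(errorRate > 0, errorRate < 1,
            nrow(alleles) == length(genotypes))
  if (!is.null(seed)) set.seed(seed)
  n <- length(genotypes)
  ref <- alleles[, 1L]; alt <- alleles[, 2L]

  depth <- stats::rpois(n, meanDepth)
  altReads <- stats::rbinom(n, depth, genotypes / 2)
  refReads <- depth - altReads

  counts <- matrix(0L, n, 4L)
  idx <- seq_len(n)
  for (origin in list(list(a = ref, r = refReads),
                      list(a = alt, r = altReads))) {
    nErr <- stats::rbinom(n, origin$r, errorRate)
    ok <- origin$r - nErr
    counts[cbind(idx, origin$a)] <- counts[cbind(idx, origin$a)] + ok
    err <- .splitErrors(nErr)
    ob <- .otherBases(origin$a)
    for (j in 1:3)
      counts[cbind(idx, ob[, j])] <- counts[cbind(idx, ob[, j])] + err[, j]
  }

  logGL10 <- counts %*% t(.logBaseGivenGeno(errorRate))
  gl10 <- exp(logGL10 - .rowMax(logGL10))
  colnames(gl10) <- genotype10Names()

  gidx <- cbind(.pairIndex[cbind(ref, ref)],
                .pairIndex[cbind(ref, alt)],
                .pairIndex[cbind(alt, alt)])
  log3 <- cbind(logGL10[cbind(idx, gidx[, 1L])],
                logGL10[cbind(idx, gidx[, 2L])],
                logGL10[cbind(idx, gidx[, 3L])])
  gl3 <- exp(log3 - .rowMax(log3))
  colnames(gl3) <- c("0", "1", "2")

  list(gl10 = gl10, gl3 = gl3, depth = depth, baseCounts = counts)
}

#' Simulate genotype likelihoods for a simulated pair
#'
#' Runs [simulateReadsGL()] for both individuals of a simulated pair and
#' wraps the results as [PairGL-class] objects in the requested
#' form(s).
#'
#' @param sim a pair simulation as returned by
#'   [simulatePairGenotypes()].
#' @param meanDepth,errorRate,seed see [simulateReadsGL()].
#' @param mode "sfs" (diallelic 3-genotype form), "ibs" (10-genotype
#'   form) or "both".
#' @return a list with elements \code{sfs} and/or \code{ibs}, each a
#'   [PairGL-class].
#' @examples
#' sim <- simulatePairGenotypes("PO", 2000, seed = 1)
#' gl <- simulatePairGL(sim, meanDepth = 8, seed = 2)
#' pairStats(emCategoryCounts(emSFS2D(gl$sfs)))
#' @export
simulatePairGL <- function(sim, meanDepth = 4, errorRate = 0.01,
                           seed = NULL, mode = c("both", "sfs", "ibs")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  r1 <- simulateReadsGL(sim$g1, sim$alleles, meanDepth, errorRate)
  r2 <- simulateReadsGL(sim$g2, sim$alleles, meanDepth, errorRate)
  out <- list()
  if (mode %in% c("both", "sfs"))
    out$sfs <- new("PairGL", contig = sim$contig, pos = sim$pos,
                   mode = "diallelic3", gl1 = r1$gl3, gl2 = r2$gl3,
                   refAllele = as.integer(sim$alleles[, 1L]),
                   altAllele = as.integer(sim$alleles[, 2L]))
  if (mode %in% c("both", "ibs"))
    out$ibs <- new("PairGL", contig = sim$contig, pos = sim$pos,
                   mode = "tengenotype10", gl1 = r1$gl10, gl2 = r2$gl10,
                   refAllele = integer(0), altAllele = integer(0))
  out
}

#' Naive genotype calling from likelihoods
#'
#' Calls, per site and individual, the genotype with the highest
#' likelihood; sites where the maximum is not unique (e.g. no reads) are
#' set to missing. This mimics basic hard-calling from low-depth data
#' and is provided as a negative control: at ~4x depth heterozygotes
#' are systematically undercalled, which biases kinship estimates of
#' related pairs downward relative to the EM estimates.
#'
#' @param pairGL a [PairGL-class] in "diallelic3" mode.
#' @return list with integer vectors \code{g1} and \code{g2} (0/1/2/NA).
#' @export
callGenotypesNaive <- function(pairGL) {
  stopifnot(is(pairGL, "PairGL"), pairGL@mode == "diallelic3")
  callOne <- function(gl) {
    mx <- .rowMax(gl)
    nmax <- (gl[, 1L] == mx) + (gl[, 2L] == mx) + (gl[, 3L] == mx)
    g <- max.col(gl, ties.method = "first") - 1L
    g[nmax > 1L] <- NA_integer_
    g
  }
  list(g1 = callOne(pairGL@gl1), g2 = callOne(pairGL@gl2))
}
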