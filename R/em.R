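#' @include readsim.R
NULL

#' @describeIn PairGL-class number of sites.
#' @param x a PairGL object.
#' @export
setMethod("nSites", "PairGL", function(x) length(x@pos))

#' @export
setMethod("[", "PairGL", function(x, i, j, ..., drop = FALSE) {
  new("PairGL", contig = x@contig[i], pos = x@pos[i], mode = x@mode,
      gl1 = x@gl1[i, , drop = FALSE], gl2 = x@gl2[i, , drop = FALSE],
      refAllele = if (length(x@refAllele)) x@refAllele[i] else integer(0),
      altAllele = if (length(x@altAllele)) x@altAllele[i] else integer(0))
})

setMethod("show", "PairGL", function(object) {
  cat(sprintf("PairGL (%s): %d sites on %d contig(s)\n", object@mode,
              nSites(object), length(unique(object@contig))))
})

## Core EM for a site x component likelihood matrix L (rows scale-free):
## maximizes prod_sites sum_k pi_k L[site, k] over the simplex.
## E-step: per-site posterior over components; M-step: mean posterior.
.emMixture <- function(L, tol = 1e-9, maxIter = 5000L) {
  n <- nrow(L); K <- ncol(L)
  if (n < 1L) stop("no sites")
  flat <- .rowMax(L) <= 0
  if (any(flat)) stop("sites with all-zero likelihood vectors")
  informative <- {
    rMin <- L[, 1L]
    for (jj in seq_len(K)[-1L]) rMin <- pmin(rMin, L[, jj])
    any(.rowMax(L) > rMin)
  }
  prop <- rep(1 / K, K)
  if (!informative) {
    warning("all likelihood vectors are flat; returning the uniform ",
            "initialization (not converged)")
    return(list(prop = prop, logLik = sum(log(L %*% prop)),
                trace = numeric(0), nIter = 0L, converged = FALSE))
  }
  trace <- numeric(maxIter)
  prevLL <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    denom <- as.vector(L %*% prop)
    ll <- sum(log(denom))
    trace[it] <- ll
    newProp <- prop * as.vector(crossprod(L, 1 / denom)) / n
    delta <- max(abs(newProp - prop))
    prop <- newProp
    if (it > 1L && (ll - prevLL < tol || delta < tol)) {
      converged <- TRUE
      break
    }
    prevLL <- ll
  }
  list(prop = prop, logLik = trace[it], trace = trace[seq_len(it)],
       nIter = it, converged = converged)
}

.asMixtureEstimate <- function(fit, n, mode, names) {
  prop <- fit$prop
  names(prop) <- names
  new("MixtureEstimate", prop = prop, counts = prop * n,
      logLik = fit$logLik, logLikTrace = fit$trace,
      nIter = fit$nIter, converged = fit$converged, mode = mode)
}

#' Two-individual SFS estimation by EM (9 categories)
#'
#' Maximum-likelihood estimation of the nine pairwise genotype-category
#' proportions A-I directly from per-site genotype likelihoods in the
#' diallelic 3-genotype form, without calling genotypes. The model is a
#' mixture over the nine joint categories with per-site likelihood
#' sum over (g1, g2) of pi(g1, g2) GL1(g1) GL2(g2); EM alternates a
#' per-site posterior over the nine cells (E-step) with the mean
#' posterior (M-step) until the log-likelihood gain or the largest
#' proportion change drops below \code{tol}.
#'
#' @param x a [PairGL-class] in "diallelic3" mode, or a list with
#'   numeric n x 3 matrices \code{gl1} and \code{gl2}.
#' @param tol convergence tolerance on the log-likelihood gain and the
#'   largest proportion change (default 1e-9: mixture weights sitting on
#'   the simplex boundary, such as the opposing-homozygote cell of a
#'   parent-offspring pair, converge slowly and a looser tolerance
#'   leaves them visibly inflated).
#' @param maxIter maximum EM iterations (default 5000).
#' @return a [MixtureEstimate-class] with 9 components in cell order
#'   a..i; expected site counts are \code{prop * nSites}.
#' @examples
#' sim <- simulatePairGenotypes("UR", 2000, seed = 3)
#' gl <- simulatePairGL(sim, seed = 4, mode = "sfs")
#' emSFS2D(gl$sfs)
#' @export
emSFS2D <- function(x, tol = 1e-9, maxIter = 5000L) {
  if (is(x, "PairGL")) {
    stopifnot(x@mode == "diallelic3")
    gl1 <- x@gl1; gl2 <- x@gl2
  } else {
    gl1 <- x$gl1; gl2 <- x$gl2
  }
  stopifnot(ncol(gl1) == 3L, ncol(gl2) == 3L, nrow(gl1) == nrow(gl2))
  i1 <- rep(1:3, each = 3L)
  i2 <- rep(1:3, times = 3L)
  L <- gl1[, i1, drop = FALSE] * gl2[, i2, drop = FALSE]
  fit <- .emMixture(L, tol, maxIter)
  .asMixtureEstimate(fit, nrow(L), "sfs9", .CELLS)
}

#' IBS-based estimation by EM (100 genotype-pair categories)
#'
#' Maximum-likelihood estimation of the proportions of all 100 (10 x 10)
#' joint genotypes of the pair from 10-genotype likelihood vectors,
#' requiring no knowledge of the alleles present at each site. Use
#' [collapseIBS()] to reduce the estimate to the A-I categories.
#'
#' @param x a [PairGL-class] in "tengenotype10" mode, or a list with
#'   n x 10 matrices \code{gl1} and \code{gl2}.
#' @param tol,maxIter as in [emSFS2D()].
#' @return a [MixtureEstimate-class] with 100 components named
#'   "g1/g2" in the 10-genotype order of [genotype10Names()].
#' @export
emIBS <- function(x, tol = 1e-9, maxIter = 5000L) {
  if (is(x, "PairGL")) {
    stopifnot(x@mode == "tengenotype10")
    gl1 <- x@gl1; gl2 <- x@gl2
  } else {
    gl1 <- x$gl1; gl2 <- x$gl2
  }
  stopifnot(ncol(gl1) == 10L, ncol(gl2) == 10L, nrow(gl1) == nrow(gl2))
  i1 <- rep(1:10, each = 10L)
  i2 <- rep(1:10, times = 10L)
  L <- gl1[, i1, drop = FALSE] * gl2[, i2, drop = FALSE]
  fit <- .emMixture(L, tol, maxIter)
  nm <- genotype10Names()
  .asMixtureEstimate(fit, nrow(L), "ibs100",
                     paste(nm[i1], nm[i2], sep = "/"))
}

## classification of each of the 100 genotype pairs by its allele union:
## returns integer code 0 = discard (>2 alleles), 1 = hom-same, 2 =
## opposing hom, 3 = het/hom sharing, 4 = het-het (same pair)
.ibsPairClass <- local({
  cls <- integer(100L)
  k <- 0L
  for (a in 1:10) for (b in 1:10) {
    k <- k + 1L
    basesA <- .GENO10[a, ]; basesB <- .GENO10[b, ]
    u <- unique(c(basesA, basesB))
    if (length(u) > 2L) { cls[k] <- 0L; next }
    hetA <- basesA[1L] != basesA[2L]
    hetB <- basesB[1L] != basesB[2L]
    cls[k] <- if (hetA && hetB) 4L
              else if (!hetA && !hetB) (if (basesA[1L] == basesB[1L]) 1L else 2L)
              else 3L
  }
  cls
})

#' Collapse a 100-category IBS estimate to the A-I categories
#'
#' Genotype pairs whose union of alleles has at most two distinct bases
#' are summed into the four aggregates that the pairwise statistics
#' consume (identical homozygotes, opposing homozygotes, het/hom,
#' double het); pairs involving more than two distinct bases (e.g.
#' AC/AG) are discarded and their total mass reported. Because the
#' 10-genotype form carries no allele orientation, the aggregate mass is
#' split evenly over the symmetric cells (a/i, c/g, b/d/f/h); every
#' statistic is invariant under this split.
#'
#' @param est a [MixtureEstimate-class] with mode "ibs100".
#' @return list with \code{counts} (a [CategoryCounts-class] of expected
#'   site counts over retained pairs) and \code{discardedFraction}.
#' @export
collapseIBS <- function(est) {
  stopifnot(is(est, "MixtureEstimate"), est@mode == "ibs100")
  cnt <- est@counts
  agg <- vapply(1:4, function(cl) sum(cnt[.ibsPairClass == cl]), numeric(1))
  homSame <- agg[1L]; opp <- agg[2L]; hetHom <- agg[3L]; e <- agg[4L]
  cc <- CategoryCounts(c(homSame / 2, hetHom / 4, opp / 2,
                         hetHom / 4, e, hetHom / 4,
                         opp / 2, hetHom / 4, homSame / 2))
  list(counts = cc,
       discardedFraction = sum(cnt[.ibsPairClass == 0L]) / sum(cnt))
}

#' Category counts from a mixture estimate
#'
#' @param est a [MixtureEstimate-class] (either mode).
#' @return a [CategoryCounts-class] of expected site counts.
#' @export
emCategoryCounts <- function(est) {
  stopifnot(is(est, "MixtureEstimate"))
  if (est@mode == "sfs9") CategoryCounts(est@counts)
  else collapseIBS(est)$counts
}

#' Per-contig EM estimation with pooling
#'
#' Analyses each contig (chromosome) separately and sums the per-contig
#' expected category counts into a genome-wide estimate, retaining the
#' per-contig counts for the chromosome block-jackknife. Analysing many
#' small chunks separately at low depth is known to bias the estimated
#' number of opposing-homozygote (IBS0) sites upward; a warning is
#' emitted when chunks are small and a single-run analysis is
#' preferable when memory allows.
#'
#' @param pairGL a [PairGL-class].
#' @param tol,maxIter EM controls, see [emSFS2D()].
#' @param minChunkSites emit the small-chunk warning when any contig has
#'   fewer sites than this (default 5000).
#' @return list with \code{perContig} (named list of
#'   [MixtureEstimate-class]), \code{blocks} (named list of per-contig
#'   [CategoryCounts-class]), \code{pooled} (their sum) and, in IBS
#'   mode, \code{discardedFraction}.
#' @export
chunkedEstimate <- function(pairGL, tol = 1e-9, maxIter = 5000L,
                            minChunkSites = 5000L) {
  stopifnot(is(pairGL, "PairGL"))
  contigs <- unique(pairGL@contig)
  sizes <- table(pairGL@contig)[contigs]
  if (any(sizes < minChunkSites))
    warning("some contigs have fewer than ", minChunkSites, " sites; ",
            "per-chromosome analysis of small data sets can bias the ",
            "IBS0 count upward - consider a single-run analysis")
  emFun <- if (pairGL@mode == "diallelic3") emSFS2D else emIBS
  perContig <- lapply(contigs, function(ct) {
    emFun(pairGL[pairGL@contig == ct], tol = tol, maxIter = maxIter)
  })
  names(perContig) <- contigs
  if (pairGL@mode == "diallelic3") {
    blocks <- lapply(perContig, emCategoryCounts)
    pooled <- Reduce(`+`, blocks)
    list(perContig = perContig, blocks = blocks, pooled = pooled)
  } else {
    coll <- lapply(perContig, collapseIBS)
    blocks <- lapply(coll, `[[`, "counts")
    pooled <- Reduce(`+`, blocks)
    disc <- sum(vapply(perContig, function(x) sum(x@counts), numeric(1)) *
                  vapply(coll, `[[`, numeric(1), "discardedFraction")) /
      sum(vapply(perContig, function(x) sum(x@counts), numeric(1)))
    list(perContig = perContig, blocks = blocks, pooled = pooled,
         discardedFraction = disc)
  }
}

#' @describeIn MixtureEstimate-class estimated proportions.
#' @param x a MixtureEstimate.
#' @export
setMethod("proportions10", "MixtureEstimate", function(x) x@prop)

#' @describeIn MixtureEstimate-class final log-likelihood.
#' @export
setMethod("emLogLik", "MixtureEstimate", function(x) x@logLik)

#' @describeIn MixtureEstimate-class convergence flag.
#' @export
setMethod("emConverged", "MixtureEstimate", function(x) x@converged)

setMethod("show", "MixtureEstimate", function(object) {
  cat(sprintf("MixtureEstimate (%s): %d components, logLik %.4f, %d iterations%s\n",
              object@mode, length(object@prop), object@logLik,
              object@nIter,
              if (object@converged) " (converged)" else " (NOT converged)"))
  if (object@mode == "sfs9") {
    cat("expected counts:\n")
    print(CategoryCounts(object@counts)@cells)
  }
})
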