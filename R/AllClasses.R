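#' @import methods
NULL

## Letters a..i index the 3x3 genotype-pair matrix row-major:
## rows = genotype of individual 1 (0,1,2 copies of the counted allele),
## columns = genotype of individual 2.
.CELLS <- c("a", "b", "c", "d", "e", "f", "g", "h", "i")

#' CategoryCounts: the nine pairwise genotype categories
#'
#' Counts (or proportions) of diallelic sites in each of the nine joint
#' genotype categories of two diploid individuals. Rows index the genotype
#' of individual 1 and columns the genotype of individual 2, both coded as
#' 0, 1 or 2 copies of an arbitrary counted allele. Every statistic
#' computed from a \code{CategoryCounts} is invariant under allele
#' relabelling and under swapping the two individuals, so the orientation
#' of the counted allele never matters.
#'
#' @slot cells numeric 3x3 matrix of non-negative cell values.
#'
#' @seealso [countPairMatrix()], [pairStats()]
#' @export
setClass("CategoryCounts", representation(cells = "matrix"))

setValidity("CategoryCounts", function(object) {
  m <- object@cells
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
    return("'cells' must be a numeric 3x3 matrix")
  if (anyNA(m) || any(!is.finite(m)))
    return("'cells' must be finite and non-missing")
  if (any(m < 0))
    return("'cells' must be non-negative")
  TRUE
})

#' KCoefficients: IBD-sharing proportions for a relationship
#'
#' The probabilities (k0, k1, k2) that a non-inbred pair of individuals
#' shares 0, 1 or 2 alleles identical by descent at a locus, together with
#' a relationship label. The kinship coefficient is
#' \eqn{\theta = k_1/4 + k_2/2}.
#'
#' @slot k numeric vector of length 3 (k0, k1, k2), non-negative, summing
#'   to one.
#' @slot label single character relationship name (e.g. "PO", "FS").
#'
#' @seealso [kCoefficients()], [thetaFromK()]
#' @export
setClass("KCoefficients", representation(k = "numeric", label = "character"))

setValidity("KCoefficients", function(object) {
  k <- object@k
  if (length(k) != 3L || anyNA(k) || any(k < 0))
    return("'k' must be three non-negative values (k0, k1, k2)")
  if (abs(sum(k) - 1) > 1e-8)
    return("k0 + k1 + k2 must equal 1")
  if (length(object@label) != 1L)
    return("'label' must be a single string")
  TRUE
})

#' SpectrumModel: an allele-frequency spectrum
#'
#' A discrete allele-frequency spectrum: a grid of population allele
#' frequencies in (0, 1) with non-negative weights summing to one. All
#' spectrum constructors (point mass, grid, beta, constant-Ne, empirical)
#' reduce to this representation. Because every pairwise statistic in this
#' package is invariant to exchanging an allele frequency p with 1 - p, a
#' folded spectrum (support restricted to p <= 1/2) is equivalent to its
#' symmetric unfolded counterpart.
#'
#' @slot kind character tag recording how the spectrum was built.
#' @slot p numeric grid of allele frequencies, strictly inside (0, 1).
#' @slot w numeric weights, same length as \code{p}, normalized to sum 1.
#'
#' @seealso [gridSpectrum()], [constantNeSpectrum()], [sampleFreq()]
#' @export
setClass("SpectrumModel",
         representation(kind = "character", p = "numeric", w = "numeric"))

setValidity("SpectrumModel", function(object) {
  p <- object@p; w <- object@w
  if (length(p) == 0L) return("spectrum grid is empty")
  if (length(p) != length(w)) return("'p' and 'w' must have equal length")
  if (anyNA(p) || any(p <= 0) || any(p >= 1))
    return("allele frequencies must lie strictly inside (0, 1)")
  if (anyNA(w) || any(w < 0)) return("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8) return("weights must sum to 1")
  TRUE
})

#' PairGL: per-site genotype likelihoods for a pair of individuals
#'
#' Container for the genotype likelihoods of two individuals at diallelic
#' sites, in one of two forms. In \code{"diallelic3"} mode each individual
#' has three likelihoods per site, for genotypes carrying 0, 1 or 2 copies
#' of the site's alternate allele given a designated known (reference)
#' allele, as in two-dimensional SFS estimation. In \code{"tengenotype10"}
#' mode each individual has ten likelihoods per site, one for every
#' unordered pair of the four bases (AA, AC, AG, AT, CC, CG, CT, GG, GT,
#' TT), requiring no prior knowledge of the alleles present.
#'
#' Likelihood vectors are scale-free: multiplying a site's vector by a
#' positive constant changes no downstream estimate. Vectors are stored on
#' the linear scale, normalized so the per-site maximum is one.
#'
#' @slot contig character contig/chromosome label per site (jackknife
#'   blocking unit).
#' @slot pos integer 1-based position per site.
#' @slot mode "diallelic3" or "tengenotype10".
#' @slot gl1,gl2 numeric matrices (sites x 3 or sites x 10) for the two
#'   individuals.
#' @slot refAllele,altAllele integer base codes 1..4 (A,C,G,T) for the
#'   designated known allele and the alternate allele; may be empty in
#'   tengenotype10 mode.
#'
#' @seealso [simulatePairGL()], [emSFS2D()], [emIBS()]
#' @export
setClass("PairGL",
         representation(contig = "character", pos = "integer",
                        mode = "character",
                        gl1 = "matrix", gl2 = "matrix",
                        refAllele = "integer", altAllele = "integer"))

setValidity("PairGL", function(object) {
  n <- length(object@pos)
  if (!object@mode %in% c("diallelic3", "tengenotype10"))
    return("mode must be 'diallelic3' or 'tengenotype10'")
  k <- if (object@mode == "diallelic3") 3L else 10L
  for (nm in c("gl1", "gl2")) {
    g <- slot(object, nm)
    if (!is.numeric(g) || nrow(g) != n || ncol(g) != k)
      return(sprintf("'%s' must be a numeric %d x %d matrix", nm, n, k))
    if (anyNA(g) || any(g < 0))
      return(sprintf("'%s' must be non-negative and non-missing", nm))
  }
  if (length(object@contig) != n)
    return("'contig' must have one label per site")
  if (object@mode == "diallelic3" &&
      (length(object@refAllele) != n || length(object@altAllele) != n))
    return("diallelic3 mode requires per-site ref and alt allele codes")
  TRUE
})

#' MixtureEstimate: EM estimate of genotype-pair category proportions
#'
#' Result of maximum-likelihood estimation (via EM) of the mixture
#' proportions over joint genotype categories: 9 components for the
#' two-individual SFS form, 100 components for the 10x10 IBS form.
#'
#' @slot prop numeric vector of estimated proportions (sums to 1).
#' @slot counts numeric vector of expected site counts (prop * n sites).
#' @slot logLik final log-likelihood.
#' @slot logLikTrace numeric per-iteration log-likelihood (non-decreasing).
#' @slot nIter number of EM iterations performed.
#' @slot converged logical convergence flag.
#' @slot mode "sfs9" or "ibs100".
#'
#' @seealso [emSFS2D()], [emIBS()], [collapseIBS()]
#' @export
setClass("MixtureEstimate",
         representation(prop = "numeric", counts = "numeric",
                        logLik = "numeric", logLikTrace = "numeric",
                        nIter = "integer", converged = "logical",
                        mode = "character"))

#' JackknifeResult: weighted block-jackknife estimate of one statistic
#'
#' @slot statistic name of the statistic.
#' @slot estimate point estimate from the pooled data.
#' @slot se weighted delete-one-block jackknife standard error.
#' @slot nBlocks number of blocks used.
#' @slot loo per-block leave-one-out estimates.
#' @slot weights per-block site counts.
#'
#' @seealso [blockJackknife()]
#' @export
setClass("JackknifeResult",
         representation(statistic = "character", estimate = "numeric",
                        se = "numeric", nBlocks = "integer",
                        loo = "numeric", weights = "numeric"))

#' ExpectationRange: attainable expectations for a relationship
#'
#' The range of the expected R0, R1 and KING-robust kinship statistics for
#' a fixed relationship (k0, k1, k2), as the allele-frequency spectrum
#' varies over all possible spectra, together with sampled points of the
#' attainable regions in the (R1, R0) and (R1, kinship) planes. Each
#' expected statistic is a ratio of two functionals that are linear in the
#' spectrum, so its extremes over all mixtures are attained on point-mass
#' spectra and the joint planar regions are traced by two-point mixtures.
#'
#' @slot relationship relationship label.
#' @slot ranges data.frame with columns statistic, min, max.
#' @slot boundary data.frame of sampled joint expectations (columns r1,
#'   r0, kinship) over single frequencies and two-point mixtures.
#'
#' @seealso [expectationRange()]
#' @export
setClass("ExpectationRange",
         representation(relationship = "character", ranges = "data.frame",
                        boundary = "data.frame"))
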