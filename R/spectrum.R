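#' @include AllClasses.R AllGenerics.R
NULL

.spectrum <- function(kind, p, w) {
  w <- w / sum(w)
  new("SpectrumModel", kind = kind, p = as.numeric(p), w = as.numeric(w))
}

#' Point-mass allele-frequency spectrum
#'
#' All sites share one population allele frequency p. Point masses are
#' the extreme spectra: the expectation of every ratio statistic over an
#' arbitrary spectrum is bracketed by its values on point masses.
#'
#' @param p allele frequency in (0, 1).
#' @export
pointSpectrum <- function(p) {
  stopifnot(length(p) == 1L, p > 0, p < 1)
  .spectrum("point_mass", p, 1)
}

#' Allele-frequency spectrum on an explicit grid
#'
#' @param p numeric grid of frequencies in (0, 1).
#' @param w non-negative weights (normalized internally).
#' @export
gridSpectrum <- function(p, w) {
  stopifnot(length(p) == length(w))
  .spectrum("grid", p, w)
}

#' Empirical spectrum from a list of allele frequencies
#'
#' Each supplied frequency gets equal weight.
#'
#' @param p numeric vector of frequencies in (0, 1).
#' @export
empiricalSpectrum <- function(p) .spectrum("empirical", p, rep(1, length(p)))

#' Beta-distributed allele-frequency spectrum
#'
#' Beta(alpha, beta) density discretized on a regular grid inside (0, 1).
#'
#' @param alpha,beta shape parameters.
#' @param nGrid number of grid points.
#' @export
betaSpectrum <- function(alpha, beta, nGrid = 512L) {
  p <- seq(1 / (2 * nGrid), 1 - 1 / (2 * nGrid), length.out = nGrid)
  .spectrum("beta", p, stats::dbeta(p, alpha, beta))
}

#' Expected spectrum for a constant-size population
#'
#' The classical neutral expectation for a sample of \code{nChrom}
#' chromosomes from a population of constant effective size: the expected
#' count of sites with j copies of the derived allele is proportional to
#' 1/j, placed at frequencies p = j / nChrom for j = 1 .. nChrom - 1.
#' The default panel of 40 chromosomes matches the reference panel used
#' for minor-allele-count ascertainment.
#'
#' @param nChrom number of sampled chromosomes (default 40).
#' @export
constantNeSpectrum <- function(nChrom = 40L) {
  j <- seq_len(nChrom - 1L)
  .spectrum("neutral_constant", j / nChrom, 1 / j)
}

#' Qualitative demography spectra
#'
#' Tilted versions of the constant-size 1/j spectrum standing in for
#' recent population-size change: growth (a recent 10-fold increase in
#' Ne) skews the spectrum toward rare variants, modelled as weights
#' proportional to 1/j^(1 + tilt); decline (10-fold decrease) skews it
#' toward common variants, 1/j^(1 - tilt). These are qualitative
#' stand-ins for coalescent-simulated demographies, not exact expected
#' spectra; all ratio statistics in this package are insensitive to the
#' exact shape.
#'
#' @param history "constant", "growth" or "decline".
#' @param nChrom number of sampled chromosomes.
#' @param tilt exponent shift used for growth/decline (default 0.5).
#' @export
demographySpectrum <- function(history = c("constant", "growth", "decline"),
                               nChrom = 40L, tilt = 0.5) {
  history <- match.arg(history)
  a <- switch(history, constant = 1, growth = 1 + tilt, decline = 1 - tilt)
  j <- seq_len(nChrom - 1L)
  .spectrum(paste0("demography_", history), j / nChrom, 1 / j^a)
}

#' @describeIn SpectrumModel-class draw n allele frequencies from the
#'   spectrum.
#' @param x a SpectrumModel.
#' @param n number of draws.
#' @export
setMethod("sampleFreq", "SpectrumModel", function(x, n) {
  if (length(x@p) == 1L) return(rep(x@p, n))
  x@p[sample.int(length(x@p), n, replace = TRUE, prob = x@w)]
})

#' Spectrum grid and weights
#'
#' @param x a SpectrumModel.
#' @return data.frame with columns p and w.
#' @export
spectrumGrid <- function(x) {
  stopifnot(is(x, "SpectrumModel"))
  data.frame(p = x@p, w = x@w)
}

setMethod("show", "SpectrumModel", function(object) {
  cat(sprintf("SpectrumModel '%s': %d grid points, p in [%.4g, %.4g]\n",
              object@kind, length(object@p), min(object@p), max(object@p)))
})
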