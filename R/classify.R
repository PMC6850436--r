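#' @include jackknife.R
NULL

## relationship labels ordered from most to least related; ties in the
## nearest-reference-point rule break toward the LESS related label.
.RELATION_ORDER <- c("PO", "FS", "HS", "C1", "UR")

#' Generate relationship reference points by simulation
#'
#' Simulates one pair per relationship (PO, FS, HS, C1, UR) under a
#' constant-population-size allele-frequency spectrum and records the
#' resulting (R1, R0) coordinate (plus kinship) as the single reference
#' point characterizing that relationship for nearest-point
#' classification. The seed and spectrum are recorded so shipped points
#' are fully regenerable.
#'
#' @param seed integer seed (default 42, the provenance of the shipped
#'   table).
#' @param nSites sites per relationship (default 5e5).
#' @param spectrum a [SpectrumModel-class]; default constant-Ne.
#' @return data.frame with columns relationship, r1, r0, kinship,
#'   nSites, seed.
#' @export
makeReferencePoints <- function(seed = 42L, nSites = 5e5,
                                spectrum = constantNeSpectrum()) {
  out <- lapply(seq_along(.RELATION_ORDER), function(i) {
    lb <- .RELATION_ORDER[i]
    sim <- simulatePairGenotypes(lb, nSites, spectrum = spectrum,
                                 seed = seed + i - 1L)
    s <- pairStats(countPairMatrix(sim$g1, sim$g2))
    data.frame(relationship = lb, r1 = s$r1, r0 = s$r0,
               kinship = s$kingKinship)
  })
  res <- do.call(rbind, out)
  res$nSites <- nSites
  res$seed <- seed
  res
}

#' Reference points shipped with the package
#'
#' Reads the precomputed (R1, R0) reference points (one per
#' relationship, simulated under a constant-Ne spectrum; provenance
#' columns record the seed and size). Regenerate with
#' [makeReferencePoints()].
#'
#' @return data.frame with columns relationship, r1, r0, kinship.
#' @export
defaultReferencePoints <- function() {
  path <- system.file("extdata", "reference_points.tsv",
                      package = "PairRelate")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Classify pairs by nearest (R1, R0) reference point
#'
#' Assigns each pair the relationship of the closest reference point in
#' the (R1, R0) plane, by Euclidean distance. Exact ties break toward
#' the less-related category. Pairs with non-finite statistics are
#' labelled "unclassifiable".
#'
#' @param r1,r0 numeric vectors of the two statistics (recycled to a
#'   common length).
#' @param refs reference-point data.frame (columns relationship, r1,
#'   r0); default the shipped constant-Ne points.
#' @return character vector of relationship labels.
#' @examples
#' classifyR1R0(0.5, 0.001)
#' @export
classifyR1R0 <- function(r1, r0, refs = defaultReferencePoints()) {
  nn <- max(length(r1), length(r0))
  r1 <- rep_len(r1, nn); r0 <- rep_len(r0, nn)
  ## order candidates most- to least-related so which.max of the
  ## reversed negative distance prefers less-related on exact ties
  ord <- order(match(refs$relationship, .RELATION_ORDER))
  refs <- refs[ord, ]
  vapply(seq_len(nn), function(i) {
    if (!is.finite(r1[i]) || !is.finite(r0[i])) return("unclassifiable")
    d <- (refs$r1 - r1[i])^2 + (refs$r0 - r0[i])^2
    best <- which(d == min(d))
    refs$relationship[best[length(best)]]
  }, character(1))
}

#' Kinship classification thresholds
#'
#' The kinship cut points separating relationship degrees, following
#' the standard KING criteria: first degree above 2^(-5/2), second
#' degree (HS) above 2^(-7/2), first cousins above 2^(-9/2), then an
#' unknown/distantly-related (UK-DR) band down to 2^(-13/2)
#' (corresponding to 4th- to 5th-degree relatives), below which pairs
#' are unrelated. Kinship above 2^(-3/2) flags duplicates/monozygotic
#' twins. First-degree pairs are split into PO vs FS with an R0 cutoff:
#' the expected R0 for parent-offspring is zero (barring mutation and
#' genotyping error), so R0 below \code{poFsR0} means PO.
#'
#' @param poFsR0 R0 cut separating PO from FS within the first-degree
#'   band (default 0.02).
#' @return list with elements \code{cuts} (named, strictly decreasing)
#'   and \code{poFsR0}.
#' @export
kinshipThresholds <- function(poFsR0 = 0.02) {
  list(cuts = c(DUP = 2^(-3 / 2), first = 2^(-5 / 2), HS = 2^(-7 / 2),
                C1 = 2^(-9 / 2), UKDR = 2^(-13 / 2)),
       poFsR0 = poFsR0)
}

#' Classify pairs by kinship bands
#'
#' Assigns a relationship degree from the estimated KING-robust kinship
#' coefficient using the threshold bands of [kinshipThresholds()], with
#' first-degree pairs split into PO and FS by the R0 cutoff. Kinship
#' between 2^(-13/2) and the first-cousin cut yields "UK-DR"
#' (unknown/distantly related); below it, "UR". Non-finite input yields
#' "unclassifiable".
#'
#' @param kinship numeric vector of kinship estimates.
#' @param r0 numeric vector of R0 estimates (used only in the
#'   first-degree band).
#' @param thresholds as returned by [kinshipThresholds()].
#' @return character vector of labels (PO, FS, HS, C1, UK-DR, UR, DUP
#'   or unclassifiable).
#' @examples
#' classifyKinship(c(0.25, 0.25, 0.01), c(0.001, 0.1, 0.5))
#' @export
classifyKinship <- function(kinship, r0,
                            thresholds = kinshipThresholds()) {
  nn <- max(length(kinship), length(r0))
  kinship <- rep_len(kinship, nn); r0 <- rep_len(r0, nn)
  cuts <- thresholds$cuts
  vapply(seq_len(nn), function(i) {
    k <- kinship[i]
    if (!is.finite(k)) return("unclassifiable")
    if (k > cuts["DUP"]) return("DUP")
    if (k > cuts["first"]) {
      if (!is.finite(r0[i])) return("unclassifiable")
      return(if (r0[i] < thresholds$poFsR0) "PO" else "FS")
    }
    if (k > cuts["HS"]) return("HS")
    if (k > cuts["C1"]) return("C1")
    if (k > cuts["UKDR"]) return("UK-DR")
    "UR"
  }, character(1))
}
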