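#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a CategoryCounts object
#'
#' Build the 3x3 pairwise genotype-category matrix from a matrix or from
#' the nine cell values a..i given row-major (a = both individuals
#' homozygous for the counted allele's complement, e = both heterozygous,
#' i = both homozygous for the counted allele; c and g are the two
#' opposing-homozygote cells).
#'
#' @param x a numeric 3x3 matrix (rows = genotype of individual 1,
#'   columns = genotype of individual 2, both 0/1/2), or a numeric vector
#'   of length 9 in row-major cell order a, b, c, d, e, f, g, h, i.
#' @return a [CategoryCounts-class] object.
#' @examples
#' CategoryCounts(c(1, 0, 0, 0, 2, 0, 0, 0, 1))
#' @export
CategoryCounts <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    stopifnot(length(x) == 9L)
    m <- matrix(as.numeric(x), 3L, 3L, byrow = TRUE)
  }
  dimnames(m) <- list(g1 = 0:2, g2 = 0:2)
  new("CategoryCounts", cells = m)
}

#' Tally the pairwise genotype-category matrix from two genotype vectors
#'
#' Counts, over all sites where both individuals have a non-missing
#' genotype, how many sites fall in each of the nine joint genotype
#' categories. Genotypes are coded 0/1/2 copies of an arbitrary per-site
#' counted allele (orientation is irrelevant: all downstream statistics
#' are invariant under allele relabelling).
#'
#' @param g1,g2 integer vectors of equal length with values 0, 1, 2 or NA.
#' @return a [CategoryCounts-class] object; sites with a missing genotype
#'   in either individual are excluded from the tally and from the site
#'   total.
#' @examples
#' cc <- countPairMatrix(c(0, 1, 2), c(2, 1, 0))
#' cells(cc)
#' @export
countPairMatrix <- function(g1, g2) {
  if (length(g1) != length(g2))
    stop("genotype vectors must have equal length")
  bad1 <- !(g1 %in% c(0L, 1L, 2L) | is.na(g1))
  bad2 <- !(g2 %in% c(0L, 1L, 2L) | is.na(g2))
  if (any(bad1) || any(bad2))
    stop("genotypes must be 0, 1, 2 or NA")
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) {
    warning("no site with non-missing genotypes in both individuals")
    return(CategoryCounts(matrix(0, 3L, 3L)))
  }
  tab <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  CategoryCounts(matrix(as.numeric(tab), 3L, 3L))
}

#' @describeIn CategoryCounts-class the 3x3 cell matrix.
#' @param x a CategoryCounts object.
#' @export
setMethod("cells", "CategoryCounts", function(x) x@cells)

#' @describeIn CategoryCounts-class total number of (pairwise complete)
#'   sites, i.e. the sum of the nine cells.
#' @export
setMethod("nSites", "CategoryCounts", function(x) sum(x@cells))

## The four aggregates the statistics consume (C+G, E, B+D+F+H, A+I).
#' @describeIn CategoryCounts-class opposing homozygotes, C + G.
#' @export
setMethod("oppHom", "CategoryCounts",
          function(x) x@cells[1L, 3L] + x@cells[3L, 1L])

#' @describeIn CategoryCounts-class double heterozygotes, E.
#' @export
setMethod("hetHet", "CategoryCounts", function(x) x@cells[2L, 2L])

#' @describeIn CategoryCounts-class one heterozygote, one homozygote:
#'   B + D + F + H.
#' @export
setMethod("hetHom", "CategoryCounts", function(x) {
  m <- x@cells
  m[1L, 2L] + m[2L, 1L] + m[2L, 3L] + m[3L, 2L]
})

#' @describeIn CategoryCounts-class identical homozygotes, A + I.
#' @export
setMethod("homSame", "CategoryCounts",
          function(x) x@cells[1L, 1L] + x@cells[3L, 3L])

#' @describeIn CategoryCounts-class exchange the counted allele at every
#'   site (a<->i, b<->h, c<->g, d<->f); all statistics are invariant.
#' @export
setMethod("relabelAlleles", "CategoryCounts", function(x) {
  CategoryCounts(x@cells[3:1, 3:1])
})

#' @describeIn CategoryCounts-class exchange the two individuals
#'   (transpose); all statistics are invariant.
#' @export
setMethod("swapIndividuals", "CategoryCounts", function(x) {
  CategoryCounts(t(x@cells))
})

setMethod("show", "CategoryCounts", function(object) {
  cat("CategoryCounts (", format(nSites(object)), " sites)\n", sep = "")
  print(object@cells)
  cat(sprintf("opposing hom (C+G) %.6g | het-het (E) %.6g | het-hom %.6g | hom-same %.6g\n",
              oppHom(object), hetHet(object), hetHom(object),
              homSame(object)))
})

## Arithmetic on counts: pooling blocks and leave-one-out differences.
#' @export
setMethod("+", signature("CategoryCounts", "CategoryCounts"),
          function(e1, e2) CategoryCounts(e1@cells + e2@cells))

#' @export
setMethod("-", signature("CategoryCounts", "CategoryCounts"),
          function(e1, e2) {
            m <- e1@cells - e2@cells
            # guard against floating-point dust when removing a block
            m[m < 0 & m > -1e-6] <- 0
            CategoryCounts(m)
          })

#' Cell values as a named vector
#'
#' @param x a CategoryCounts object.
#' @return named numeric vector with elements a..i in row-major order.
#' @export
cellVector <- function(x) {
  v <- as.numeric(t(x@cells))
  names(v) <- .CELLS
  v
}
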