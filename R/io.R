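#' @include classify.R
NULL

## atomic write: assemble in a temp file next to the target, then rename
.atomicWrite <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path)
  invisible(path)
}

#' Read genotypes (and PL likelihoods) for selected samples from a VCF
#'
#' Parses a VCF, keeps biallelic SNP records only (multi-allelic and
#' non-SNP records are skipped and counted), and returns per-sample
#' genotype dosages coded as copies of the ALT allele (0/1/2, NA for
#' missing) plus, when the PL FORMAT field is present, linear-scale
#' genotype likelihoods 10^(-PL/10) in diallelic 3-genotype form.
#' Positions are 1-based as in the VCF.
#'
#' The counted-allele orientation (ALT) is irrelevant to all statistics
#' (allele-relabel invariance) but is fixed for reproducible cell-level
#' output.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples character vector of sample ids to extract; NULL for
#'   all.
#' @return list with \code{sites} (data.frame contig, pos, ref, alt),
#'   \code{genotypes} (sites x samples integer matrix), \code{gl}
#'   (named list of sites x 3 likelihood matrices, or NULL when no PL),
#'   and \code{skipped} (named counts of dropped records).
#' @export
readPairVCF <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  snp <- fix$REF %in% .BASES & fix$ALT %in% .BASES
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  keep <- snp & !multi
  skipped <- c(multiallelic = sum(multi), nonSNP = sum(!snp & !multi))
  if (any(!keep))
    message(sprintf("skipped %d multi-allelic and %d non-SNP record(s)",
                    skipped[["multiallelic"]], skipped[["nonSNP"]]))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  available <- colnames(gt)
  if (is.null(samples)) samples <- available
  missing <- setdiff(samples, available)
  if (length(missing))
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "),
         "; available: ", paste(available, collapse = ", "))
  gt <- gt[keep, samples, drop = FALSE]

  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  geno <- (a1 == "1") + (a2 == "1")
  geno[a1 == "." | a2 == "." | is.na(gt) | nchar(gt) < 3L] <- NA_integer_
  mode(geno) <- "integer"

  gl <- NULL
  if (any(grepl("(^|:)PL(:|$)", vcf@gt[, "FORMAT"]))) {
    pl <- vcfR::extract.gt(vcf, element = "PL")[keep, samples, drop = FALSE]
    gl <- lapply(samples, function(s) {
      parts <- strsplit(pl[, s], ",", fixed = TRUE)
      m <- matrix(NA_real_, length(parts), 3L)
      okLen <- lengths(parts) == 3L
      m[okLen, ] <- suppressWarnings(
        matrix(as.numeric(unlist(parts[okLen])), ncol = 3L, byrow = TRUE))
      out <- 10^(-m / 10)
      out[is.na(out)] <- 1  # missing PL carries no information
      out
    })
    names(gl) <- samples
  }

  list(sites = data.frame(contig = fix$CHROM[keep],
                          pos = as.integer(fix$POS[keep]),
                          ref = fix$REF[keep], alt = fix$ALT[keep],
                          stringsAsFactors = FALSE),
       genotypes = geno, gl = gl, skipped = skipped)
}

#' Read a beagle-format genotype-likelihood file
#'
#' Beagle GL text: a header line, then one row per site with columns
#' marker ("contig_position"), allele1, allele2 (base codes 0-3 for
#' A,C,G,T or bases), and three likelihood columns per individual.
#'
#' @param path beagle file (plain or gzipped).
#' @return list with \code{sites} (contig, pos, ref, alt as base codes
#'   1..4), \code{gl} (list of sites x 3 matrices per individual) and
#'   \code{ids}.
#' @export
readBeagleGL <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t",
                           data.table = FALSE)
  if ((ncol(tab) - 3L) %% 3L != 0L || ncol(tab) < 6L)
    stop("malformed beagle file: ", ncol(tab),
         " columns; need 3 site columns plus 3 per individual")
  nInd <- (ncol(tab) - 3L) %/% 3L
  marker <- as.character(tab[[1L]])
  us <- regexpr("_[^_]*$", marker)
  if (any(us < 0))
    stop("malformed marker token (expected 'contig_position') at line ",
         which(us < 0)[1L] + 1L)
  contig <- substr(marker, 1L, us - 1L)
  pos <- suppressWarnings(as.integer(substring(marker, us + 1L)))
  if (anyNA(pos))
    stop("malformed marker token (non-numeric position) at line ",
         which(is.na(pos))[1L] + 1L)
  toBase <- function(x) {
    if (is.numeric(x)) return(as.integer(x) + 1L)
    m <- match(toupper(as.character(x)), .BASES)
    ifelse(is.na(m), as.integer(x) + 1L, m)
  }
  ids <- unique(sub("\\.\\d+$", "", colnames(tab)[-(1:3)]))
  if (length(ids) != nInd) ids <- paste0("ind", seq_len(nInd))
  gl <- lapply(seq_len(nInd), function(i) {
    m <- as.matrix(tab[, 3L + (i - 1L) * 3L + 1:3])
    dimnames(m) <- list(NULL, c("0", "1", "2"))
    m
  })
  names(gl) <- ids
  list(sites = data.frame(contig = contig, pos = pos,
                          ref = toBase(tab[[2L]]), alt = toBase(tab[[3L]]),
                          stringsAsFactors = FALSE),
       gl = gl, ids = ids)
}

#' Write a beagle-format genotype-likelihood file
#'
#' @param pairGL a [PairGL-class] in "diallelic3" mode.
#' @param path output path (written atomically).
#' @param ids the two individual ids.
#' @return the path, invisibly.
#' @export
writeBeagleGL <- function(pairGL, path, ids = c("ind1", "ind2")) {
  stopifnot(is(pairGL, "PairGL"), pairGL@mode == "diallelic3")
  tab <- data.frame(marker = paste0(pairGL@contig, "_", pairGL@pos),
                    allele1 = pairGL@refAllele - 1L,
                    allele2 = pairGL@altAllele - 1L)
  tab <- cbind(tab, pairGL@gl1, pairGL@gl2)
  colnames(tab) <- c("marker", "allele1", "allele2",
                     rep(ids, each = 3L))
  .atomicWrite(function(tmp) {
    data.table::fwrite(tab, tmp, sep = "\t", quote = FALSE)
  }, path)
}

#' Write a 10-genotype likelihood table
#'
#' Tab-separated dialect for the IBS (10-genotype) likelihood form: one
#' row per site with columns contig, pos, then ten likelihood columns
#' per individual named id.AA .. id.TT in the order of
#' [genotype10Names()].
#'
#' @param pairGL a [PairGL-class] in "tengenotype10" mode.
#' @param path output path (written atomically).
#' @param ids the two individual ids.
#' @export
writeGL10 <- function(pairGL, path, ids = c("ind1", "ind2")) {
  stopifnot(is(pairGL, "PairGL"), pairGL@mode == "tengenotype10")
  tab <- data.frame(contig = pairGL@contig, pos = pairGL@pos)
  tab <- cbind(tab, pairGL@gl1, pairGL@gl2)
  colnames(tab) <- c("contig", "pos",
                     paste(rep(ids, each = 10L), genotype10Names(),
                           sep = "."))
  .atomicWrite(function(tmp) {
    data.table::fwrite(tab, tmp, sep = "\t", quote = FALSE)
  }, path)
}

#' Read a 10-genotype likelihood table written by [writeGL10()]
#'
#' @param path input path.
#' @return a [PairGL-class] in "tengenotype10" mode.
#' @export
readGL10 <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t",
                           data.table = FALSE)
  if ((ncol(tab) - 2L) %% 10L != 0L || ncol(tab) != 22L)
    stop("malformed 10-genotype GL table: expected 2 + 2 x 10 columns")
  new("PairGL", contig = as.character(tab[[1L]]),
      pos = as.integer(tab[[2L]]), mode = "tengenotype10",
      gl1 = as.matrix(tab[, 2L + 1:10]),
      gl2 = as.matrix(tab[, 12L + 1:10]),
      refAllele = integer(0), altAllele = integer(0))
}

#' Write simulated genotypes as a minimal GT-only VCF
#'
#' @param sim a simulation from [simulatePairGenotypes()] or
#'   [simulateCrossPopulationPair()].
#' @param path output path (written atomically).
#' @param ids sample names.
#' @export
writeSimVcf <- function(sim, path, ids = c("ind1", "ind2")) {
  n <- length(sim$g1)
  if (!is.null(sim$alleles)) {
    ref <- .BASES[sim$alleles[, 1L]]
    alt <- .BASES[sim$alleles[, 2L]]
  } else {
    ref <- rep("A", n); alt <- rep("C", n)
  }
  gtStr <- function(g) c("0/0", "0/1", "1/1")[g + 1L]
  body <- paste(sim$contig, sim$pos, ".", ref, alt, ".", "PASS", ".",
                "GT", gtStr(sim$g1), gtStr(sim$g2), sep = "\t")
  .atomicWrite(function(tmp) {
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=PairRelate",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", ids),
                       collapse = "\t"),
                 body), tmp)
  }, path)
}

#' Pairwise statistics for all pairs in a genotype matrix
#'
#' Tallies the category matrix and computes all six statistics for every
#' pair of columns of a genotype matrix; with contig labels, adds
#' chromosome block-jackknife standard errors and the two relationship
#' classifications.
#'
#' @param genotypes sites x individuals integer matrix (0/1/2/NA) with
#'   column names as ids.
#' @param contig optional contig label per site; enables jackknife SEs.
#' @param classify add class_r1r0 / class_kinship columns (default TRUE).
#' @param refs reference points for [classifyR1R0()].
#' @return data.frame with one row per pair: ids, nSites, the nine cell
#'   counts, the statistics (and se_ columns when contig is given), and
#'   the classifications.
#' @export
allPairStats <- function(genotypes, contig = NULL, classify = TRUE,
                         refs = defaultReferencePoints()) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) >= 2L)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(genotypes)))
  pairs <- utils::combn(ncol(genotypes), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(pi) {
    i <- pairs[1L, pi]; j <- pairs[2L, pi]
    cc <- countPairMatrix(genotypes[, i], genotypes[, j])
    row <- cbind(data.frame(id1 = ids[i], id2 = ids[j]),
                 as.data.frame(t(cellVector(cc))), pairStats(cc))
    if (!is.null(contig)) {
      jk <- jackknifeStats(perBlockCounts(genotypes[, i], genotypes[, j],
                                          contig))
      se <- stats::setNames(jk$se, paste0("se_", jk$statistic))
      row <- cbind(row, as.data.frame(t(se)))
    }
    row
  })
  res <- do.call(rbind, rows)
  if (classify) {
    res$class_r1r0 <- classifyR1R0(res$r1, res$r0, refs = refs)
    res$class_kinship <- classifyKinship(res$kingKinship, res$r0)
  }
  res
}

#' Write a results (or any) table as TSV
#'
#' @param tab data.frame.
#' @param path output path (written atomically).
#' @export
writeResultsTSV <- function(tab, path) {
  .atomicWrite(function(tmp) {
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}
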