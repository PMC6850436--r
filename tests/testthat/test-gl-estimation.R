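test_that("hard-call (one-hot) likelihoods reproduce the genotype tally exactly", {
  set.seed(50)
  g1 <- sample(0:2, 2000, replace = TRUE, prob = c(.4, .4, .2))
  g2 <- sample(0:2, 2000, replace = TRUE, prob = c(.3, .5, .2))
  truth <- cells(countPairMatrix(g1, g2))

  est <- emSFS2D(list(gl1 = oneHot3(g1), gl2 = oneHot3(g2)))
  expect_equal(unname(cells(emCategoryCounts(est))), unname(truth))
  expect_true(emConverged(est))

  # a single EM step already lands on the exact tally
  est1 <- emSFS2D(list(gl1 = oneHot3(g1), gl2 = oneHot3(g2)), maxIter = 1L)
  expect_equal(unname(cells(CategoryCounts(est1@counts))), unname(truth))

  # 10-genotype form: same genotypes expressed as base pairs
  ref <- sample.int(4, 2000, replace = TRUE)
  alt <- ((ref + sample.int(3, 2000, replace = TRUE) - 1) %% 4) + 1
  est10 <- emIBS(list(gl1 = oneHot10(g1, ref, alt),
                      gl2 = oneHot10(g2, ref, alt)))
  co <- collapseIBS(est10)
  expect_equal(co$discardedFraction, 0)
  expect_equal(oppHom(co$counts), truth[1, 3] + truth[3, 1])
  expect_equal(hetHet(co$counts), truth[2, 2])
  expect_equal(homSame(co$counts), truth[1, 1] + truth[3, 3])
  expect_equal(nSites(co$counts), 2000)
})

test_that("one EM iteration matches hand-executed E/M arithmetic", {
  # two sites, likelihoods chosen so the posterior is computable by hand
  gl1 <- rbind(c(1, 0.5, 0), c(0, 1, 0))
  gl2 <- rbind(c(1, 0, 0), c(0, 0.2, 1))
  est <- emSFS2D(list(gl1 = gl1, gl2 = gl2), maxIter = 1L)
  # site 1: joint likelihoods pi_uniform * L over the 9 cells:
  #   cells a (0,0): 1*1 = 1 ; d (1,0): 0.5*1 = 0.5; all others 0
  #   posterior: a = 2/3, d = 1/3
  # site 2: e (1,1): 1*0.2 = 0.2 ; f (1,2): 1*1 = 1
  #   posterior: e = 1/6, f = 5/6
  expected <- c(a = 2 / 3, b = 0, c = 0, d = 1 / 3, e = 1 / 6, f = 5 / 6,
                g = 0, h = 0, i = 0) / 2
  expect_equal(est@prop, expected)
  # run to convergence: the ML optimum is computable by hand.
  # Maximize log(pi_a + pi_d/2) + log(pi_e/5 + pi_f) on the simplex:
  # all mass goes to the best-supported cell of each site, so
  # pi_a = pi_f = 1/2 and the dominated cells d, e vanish.
  est2 <- emSFS2D(list(gl1 = gl1, gl2 = gl2), tol = 1e-12, maxIter = 5000L)
  expect_equal(unname(est2@prop[c("a", "f")]), c(0.5, 0.5),
               tolerance = 1e-4)
  expect_lt(sum(est2@prop[c("d", "e")]), 1e-3)
})

test_that("likelihood rescaling per site does not change estimates", {
  sim <- simulatePairGenotypes("FS", 3000, seed = 51)
  gl <- simulatePairGL(sim, meanDepth = 4, seed = 52, mode = "both")
  for (obj in gl) {
    set.seed(53)
    sc1 <- exp(runif(nSites(obj), -3, 3))
    sc2 <- exp(runif(nSites(obj), -3, 3))
    scaled <- obj
    scaled@gl1 <- obj@gl1 * sc1
    scaled@gl2 <- obj@gl2 * sc2
    emFun <- if (obj@mode == "diallelic3") emSFS2D else emIBS
    expect_equal(emFun(scaled)@prop, emFun(obj)@prop, tolerance = 1e-12)
  }
})

test_that("EM log-likelihood never decreases", {
  for (seed in c(60, 61)) {
    sim <- simulatePairGenotypes("HS", 4000, seed = seed)
    gl <- simulatePairGL(sim, meanDepth = 2, seed = seed + 100, mode = "both")
    for (est in list(emSFS2D(gl$sfs), emIBS(gl$ibs))) {
      expect_true(all(diff(est@logLikTrace) > -1e-9))
      expect_true(emConverged(est))
    }
  }
})

test_that("flat likelihoods return the uniform initialization with a warning", {
  flat <- list(gl1 = matrix(1, 50, 3), gl2 = matrix(1, 50, 3))
  expect_warning(est <- emSFS2D(flat), "flat")
  expect_equal(unname(est@prop), rep(1 / 9, 9))
  expect_false(emConverged(est))
})

test_that("IBS collapse routes allele unions to the right aggregates", {
  nm <- genotype10Names()
  mkEst <- function(w) {
    new("MixtureEstimate", prop = w / sum(w), counts = w,
        logLik = 0, logLikTrace = numeric(0), nIter = 1L,
        converged = TRUE, mode = "ibs100")
  }
  unit <- function(first, second) {
    w <- numeric(100)
    names(w) <- paste(rep(nm, each = 10), rep(nm, 10), sep = "/")
    w[paste(first, second, sep = "/")] <- 1
    w
  }
  # AA/CC: opposing homozygotes
  co <- collapseIBS(mkEst(unit("AA", "CC")))
  expect_equal(oppHom(co$counts), 1)
  expect_equal(co$discardedFraction, 0)
  # AC/AG involves three alleles: all mass discarded
  co <- collapseIBS(mkEst(unit("AC", "AG")))
  expect_equal(nSites(co$counts), 0)
  expect_equal(co$discardedFraction, 1)
  # AC/AC: double heterozygote; GT/GG: het-hom; TT/TT: identical hom
  expect_equal(hetHet(collapseIBS(mkEst(unit("AC", "AC")))$counts), 1)
  expect_equal(hetHom(collapseIBS(mkEst(unit("GT", "GG")))$counts), 1)
  expect_equal(homSame(collapseIBS(mkEst(unit("TT", "TT")))$counts), 1)

  # uniform mass: discarded fraction equals the enumerated share of
  # genotype pairs whose allele union exceeds two bases
  pairsOf <- function(x) strsplit(x, "")[[1]]
  over2 <- outer(nm, nm, Vectorize(function(x, y)
    length(unique(c(pairsOf(x), pairsOf(y)))) > 2))
  co <- collapseIBS(mkEst(rep(1, 100)))
  expect_equal(co$discardedFraction, mean(over2))
})

test_that("consistent permutation of the 10-genotype ordering leaves estimates invariant", {
  sim <- simulatePairGenotypes("UR", 2000, seed = 70)
  gl <- simulatePairGL(sim, meanDepth = 4, seed = 71, mode = "ibs")$ibs
  est <- emIBS(gl)
  set.seed(72)
  perm <- sample(10)
  permuted <- gl
  permuted@gl1 <- gl@gl1[, perm]
  permuted@gl2 <- gl@gl2[, perm]
  estP <- emIBS(permuted)
  # joint components permute accordingly: component (k1, k2) of the
  # permuted problem is component (perm[k1], perm[k2]) of the original,
  # with joint indices laid out row-major
  jointPerm <- as.vector(t(outer(perm, perm,
                                 function(a, b) (a - 1) * 10 + b)))
  expect_equal(unname(estP@prop), unname(est@prop[jointPerm]),
               tolerance = 1e-9)
})

test_that("per-contig estimation pools to the single-run answer on hard calls", {
  set.seed(80)
  g1 <- sample(0:2, 3000, replace = TRUE)
  g2 <- sample(0:2, 3000, replace = TRUE)
  pg <- new("PairGL", contig = rep(c("chrA", "chrB"), each = 1500),
            pos = rep(1:1500, 2) * 10L, mode = "diallelic3",
            gl1 = oneHot3(g1), gl2 = oneHot3(g2),
            refAllele = rep(1L, 3000), altAllele = rep(2L, 3000))
  ch <- suppressWarnings(chunkedEstimate(pg))
  expect_equal(length(ch$perContig), 2)
  expect_equal(unname(cells(ch$pooled)),
               unname(cells(countPairMatrix(g1, g2))))
  # single contig: pooled equals the per-contig estimate
  one <- pg[pg@contig == "chrA"]
  ch1 <- suppressWarnings(chunkedEstimate(one))
  expect_equal(cells(ch1$pooled), cells(ch1$blocks[[1]]))
  # small chunks trigger the per-chromosome bias warning
  expect_warning(chunkedEstimate(pg), "single-run")
})

test_that("high-depth IBS EM recovers genotype counts within one percent", {
  sim <- simulatePairGenotypes("FS", 20000, seed = 81)
  gl <- simulatePairGL(sim, meanDepth = 30, errorRate = 0.01, seed = 82,
                       mode = "ibs")
  est <- emIBS(gl$ibs)
  co <- collapseIBS(est)
  truth <- countPairMatrix(sim$g1, sim$g2)
  expect_lt(abs(hetHet(co$counts) - hetHet(truth)) / hetHet(truth), 0.01)
  expect_lt(abs(hetHom(co$counts) - hetHom(truth)) / hetHom(truth), 0.01)
  expect_lt(abs(homSame(co$counts) - homSame(truth)) / homSame(truth), 0.01)
  s <- pairStats(co$counts)
  st <- pairStats(truth)
  expect_lt(abs(s$kingKinship - st$kingKinship), 0.005)
})
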