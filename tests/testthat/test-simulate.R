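test_that("realized IBD fractions follow the relationship coefficients", {
  sim <- simulatePairGenotypes("PO", 2e4, seed = 1)
  expect_equal(unname(sim$kRealized), c(0, 1, 0))      # PO is all IBD-1
  expect_false(anyNA(sim$g1) || anyNA(sim$g2))
  fs <- simulatePairGenotypes("FS", 5e4, seed = 2)
  # binomial convergence at rate n^-1/2
  expect_lt(max(abs(fs$kRealized - c(0.25, 0.5, 0.25))), 4 * sqrt(0.25 / 5e4))
  expect_equal(sum(fs$kRealized), 1)
})

test_that("simulation is seed-deterministic and parameterized as configured", {
  a <- simulatePairGenotypes("HS", 5000, seed = 9)
  b <- simulatePairGenotypes("HS", 5000, seed = 9)
  expect_identical(a$g1, b$g1)
  expect_identical(a$g2, b$g2)
  expect_equal(length(unique(a$contig)), 22)
  expect_true(all(a$panelMinorCount >= 1))              # panel-polymorphic
  expect_true(all(a$alleles[, 1] != a$alleles[, 2]))
  c1 <- simulatePairGenotypes("HS", 5000, seed = 10)
  expect_false(identical(a$g1, c1$g1))
})

test_that("unrelated pairs obey the allele-frequency-free null", {
  sim <- simulatePairGenotypes("UR", 2e5, seed = 3,
                               spectrum = betaSpectrum(1, 3))
  jk <- jackknifeStats(perBlockCounts(sim$g1, sim$g2, sim$contig))
  r0row <- jk[jk$statistic == "r0", ]
  expect_lt(abs(r0row$estimate - 0.5), 3 * r0row$se)
  leerow <- jk[jk$statistic == "lee", ]
  expect_lt(abs(leerow$estimate - 2 / 3), 3 * leerow$se)
})

test_that("full siblings at p = 1/2 recover kinship 1/4", {
  sim <- simulatePairGenotypes("FS", 2e5, seed = 4,
                               spectrum = pointSpectrum(0.5))
  jk <- jackknifeStats(perBlockCounts(sim$g1, sim$g2, sim$contig))
  krow <- jk[jk$statistic == "kingKinship", ]
  expect_lt(abs(krow$estimate - 0.25), 3 * krow$se)
  r0row <- jk[jk$statistic == "r0", ]
  expect_lt(abs(r0row$estimate - 0.1), 3 * r0row$se)
})

test_that("cross-population pairs push R0 up and Lee down", {
  base <- simulateCrossPopulationPair(0, 1e5, seed = 5)
  st0 <- pairStats(countPairMatrix(base$g1, base$g2))
  expect_lt(abs(st0$r0 - 0.5), 0.03)        # fst = 0 collapses to UR
  expect_lt(abs(st0$lee - 2 / 3), 0.01)
  div <- simulateCrossPopulationPair(0.2, 1e5, seed = 6)
  st <- pairStats(countPairMatrix(div$g1, div$g2))
  expect_gt(st$r0, 0.5)
  expect_lt(st$lee, 2 / 3)
  expect_lt(st$kingKinship, 0)              # downward-biased, as expected
  expect_error(simulateCrossPopulationPair(1.2, 10))
})

test_that("minor-allele-count ascertainment follows the >2 of 40 rule", {
  expect_equal(ascertainSites(c(2L, 3L, 0L, 20L), minMac = 3L),
               c(FALSE, TRUE, FALSE, TRUE))
  expect_true(all(ascertainSites(c(2L, 3L), minMac = NULL)))
  # in-simulator rejection sampling enforces the same rule
  sim <- simulatePairGenotypes("UR", 5000, seed = 7,
                               ascertainment = list(minMac = 3))
  expect_true(all(sim$panelMinorCount >= 3))
  expect_equal(length(sim$g1), 5000)
})

test_that("incompatible ascertainment fails after bounded rejection", {
  expect_error(
    simulatePairGenotypes("UR", 100, spectrum = pointSpectrum(1e-4),
                          seed = 8, ascertainment = list(minMac = 15),
                          maxRounds = 3L),
    "rejection")
})

test_that("window subsetting keeps sites in sampled non-overlapping windows", {
  # 4000 sites per contig at 50 bp spacing -> contig span 200000 bp,
  # exactly 1000 windows of 200 bp per contig
  sim <- simulatePairGenotypes("UR", 88000, seed = 20)
  total <- 22 * 1000
  # identity subset: selecting every window keeps every site
  expect_true(all(subsetWindows(sim$contig, sim$pos, nWindows = total,
                                seed = 21)))
  # expected retained base pairs = nWindows x 200 -> ~4 sites per window
  m <- subsetWindows(sim$contig, sim$pos, nWindows = 5000, seed = 22)
  expect_equal(sum(m), 5000 * 4)
  expect_error(subsetWindows(sim$contig, sim$pos, nWindows = total + 1),
               "exceeds")
  # two seeds give different subsets whose statistics agree within CIs
  m2 <- subsetWindows(sim$contig, sim$pos, nWindows = 5000, seed = 23)
  expect_false(identical(m, m2))
  jkA <- jackknifeStats(perBlockCounts(sim$g1[m], sim$g2[m], sim$contig[m]))
  jkB <- jackknifeStats(perBlockCounts(sim$g1[m2], sim$g2[m2], sim$contig[m2]))
  for (st in c("r0", "r1", "kingKinship")) {
    a <- jkA[jkA$statistic == st, ]; b <- jkB[jkB$statistic == st, ]
    expect_lt(abs(a$estimate - b$estimate),
              4 * sqrt(a$se^2 + b$se^2))
  }
})

test_that("read simulation produces the stated likelihood model", {
  sim <- simulatePairGenotypes("UR", 3000, seed = 30)
  rs <- simulateReadsGL(sim$g1, sim$alleles, meanDepth = 1, errorRate = 0.01,
                        seed = 31)
  # sites with no reads carry flat likelihoods in both forms
  zero <- rs$depth == 0
  expect_true(any(zero))
  expect_true(all(abs(rs$gl10[zero, ] - 1) < 1e-12))
  expect_true(all(abs(rs$gl3[zero, ] - 1) < 1e-12))
  # a single observed read: direct evaluation of the error model.
  # GL(bb) = 0.99 for the matching homozygote and GL(bx) =
  # 0.99/2 + (0.01/3)/2 for any het containing it; normalized so the
  # homozygote is 1, every such het must equal 0.50168.../0.99
  one <- which(rs$depth == 1)
  i <- one[1]
  b <- which(rs$baseCounts[i, ] == 1)
  nm <- genotype10Names()
  hom <- paste0(c("A", "C", "G", "T")[b], c("A", "C", "G", "T")[b])
  expect_equal(unname(rs$gl10[i, hom]), 1)
  hets <- setdiff(grep(c("A", "C", "G", "T")[b], nm, value = TRUE), hom)
  expect_equal(unname(rs$gl10[i, hets]),
               rep((0.5 * 0.99 + 0.5 * 0.01 / 3) / 0.99, 3))
  # genotypes without the observed base: (0.01/3)/0.99 for homozygotes
  othersHom <- setdiff(nm[c(1, 5, 8, 10)], hom)
  expect_equal(unname(rs$gl10[i, othersHom]),
               rep((0.01 / 3) / 0.99, 3))
  expect_error(simulateReadsGL(sim$g1, sim$alleles, meanDepth = 0),
               "positive")
})

test_that("high depth makes the likelihood argmax recover the genotype", {
  sim <- simulatePairGenotypes("UR", 5000, seed = 32)
  gl <- simulatePairGL(sim, meanDepth = 100, errorRate = 0.01, seed = 33,
                       mode = "sfs")
  called <- callGenotypesNaive(gl$sfs)
  expect_gt(mean(called$g1 == sim$g1, na.rm = TRUE), 0.999)
  expect_gt(mean(called$g2 == sim$g2, na.rm = TRUE), 0.999)
})
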