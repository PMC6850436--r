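test_that("IBD-conditional cell matrices match brute-force enumeration", {
  for (p in c(0.1, 0.35, 0.5, 0.8)) {
    m <- ibdConditionalCells(p)
    # each conditional distribution is proper
    for (x in m) expect_equal(sum(x), 1)
    # pure IBD states against the founder-enumeration oracle
    expect_equal(unname(m$ibd0), bruteCellProbs(c(1, 0, 0), p))
    expect_equal(unname(m$ibd1), bruteCellProbs(c(0, 1, 0), p))
    expect_equal(unname(m$ibd2), bruteCellProbs(c(0, 0, 1), p))
  }
  # spot values at p = 1/2
  m <- ibdConditionalCells(0.5)
  expect_equal(unname(diag(m$ibd2)), c(0.25, 0.5, 0.25))
  expect_equal(unname(m$ibd1["1", "1"]), 0.25)
  expect_equal(unname(m$ibd1["0", "2"]), 0)
  expect_equal(unname(m$ibd0), outer(hwProbs(0.5), hwProbs(0.5)),
               ignore_attr = TRUE)
  expect_error(ibdConditionalCells(0), "inside")
  expect_error(ibdConditionalCells(1.2), "inside")
})

test_that("expected cells reproduce the relationship anchors", {
  po <- expectedCells("PO", pointSpectrum(0.5))
  expect_equal(hetHet(po), 0.25)
  expect_equal(oppHom(po), 0)
  s <- pairStats(po)
  expect_equal(s$r1, 0.5)
  expect_equal(s$r0, 0)

  fs <- pairStats(expectedCells("FS", pointSpectrum(0.5)))
  expect_equal(fs$r0, 0.1)
  expect_equal(fs$r1, 10 / 13, tolerance = 1e-10)  # 0.7692
  expect_equal(fs$kingKinship, 0.25)
})

test_that("expected cells are a proper mixture over any spectrum", {
  set.seed(5)
  specs <- list(pointSpectrum(0.123), betaSpectrum(0.8, 2),
                constantNeSpectrum(), empiricalSpectrum(runif(30, .01, .99)))
  for (sp in specs) for (lb in c("PO", "FS", "HS", "C1", "UR")) {
    cc <- expectedCells(lb, sp)
    expect_equal(nSites(cc), 1)
    expect_true(all(cells(cc) >= 0))
  }
  # UR closed form: kinship 0, r0 1/2 for every spectrum
  for (sp in specs) {
    s <- pairStats(expectedCells("UR", sp))
    expect_equal(s$r0, 0.5)
    expect_equal(s$kingKinship, 0, tolerance = 1e-12)
    expect_equal(s$lee, 2 / 3)
  }
})

test_that("degenerate spectra are rejected at construction", {
  expect_error(pointSpectrum(0))
  expect_error(pointSpectrum(1))
  expect_error(gridSpectrum(c(0, 0.5), c(1, 1)), "inside")
})

test_that("expectation ranges: PO degenerates to a point, UR to the null", {
  po <- expectationRange("PO")
  expect_equal(po@ranges$min, po@ranges$max)
  expect_equal(po@ranges$min[po@ranges$statistic == "r1"], 0.5)
  expect_equal(po@ranges$min[po@ranges$statistic == "r0"], 0)
  expect_equal(po@ranges$min[po@ranges$statistic == "kinship"], 0.25)

  ur <- expectationRange("UR")
  expect_equal(ur@ranges$min[ur@ranges$statistic == "r0"], 0.5)
  expect_equal(ur@ranges$max[ur@ranges$statistic == "r0"], 0.5)
  expect_equal(ur@ranges$min[ur@ranges$statistic == "kinship"], 0,
               tolerance = 1e-12)
  expect_equal(ur@ranges$max[ur@ranges$statistic == "kinship"], 0,
               tolerance = 1e-12)
  expect_error(expectationRange("FS", pGrid = numeric(0)), "empty")
})

test_that("point-mass grid scan brackets the FS R0 range", {
  # independent oracle: direct scan of expected-cell statistics on a
  # coarse grid; extremes must lie inside the reported range and the
  # range endpoints must be attained near p -> 0 and p = 1/2
  er <- expectationRange("FS")
  scan <- vapply(seq(0.001, 0.5, length.out = 101), function(p) {
    s <- pairStats(expectedCells("FS", pointSpectrum(p)))
    s$r0
  }, numeric(1))
  rng <- er@ranges[er@ranges$statistic == "r0", ]
  expect_gte(min(scan), rng$min - 1e-9)
  expect_lte(max(scan), rng$max + 1e-9)
  expect_equal(rng$max, 0.1, tolerance = 1e-6)   # attained at p = 1/2
  expect_lt(rng$min, 1e-3)                       # -> 0 as p -> 0
})

test_that("joint expectation regions of distinct relationships do not overlap", {
  ers <- lapply(c("PO", "FS", "HS", "C1", "UR"), expectationRange)
  names(ers) <- c("PO", "FS", "HS", "C1", "UR")
  cloud <- function(x) as.matrix(x@boundary[, c("r1", "r0")])
  minDist <- function(a, b) {
    m <- Inf
    for (i in seq(1, nrow(a), by = 11))
      m <- min(m, sqrt(min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)))
    m
  }
  labs <- c("FS", "HS", "C1", "UR")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gt(minDist(cloud(ers[[labs[i]]]), cloud(ers[[labs[j]]])), 0.02)
  }
  # the PO point touches the FS region (in its p -> 0 limit) but stays
  # clear of HS, C1 and UR
  poPt <- matrix(c(0.5, 0), 1, 2)
  expect_lt(minDist(poPt, cloud(ers$FS)), 0.02)
  for (lb in c("HS", "C1", "UR"))
    expect_gt(minDist(poPt, cloud(ers[[lb]])), 0.05)
})

test_that("simulated statistics fall inside the expectation machinery's predictions", {
  # per relationship x demography, genotype statistics on 1e5 simulated
  # sites must match the expected-cell statistics within Monte-Carlo
  # error (3 chromosome-jackknife SEs, floored at a small absolute slack)
  seed <- 400
  for (lb in c("PO", "FS", "HS", "C1", "UR")) {
    for (hist in c("constant", "growth", "decline")) {
      seed <- seed + 1
      sp <- demographySpectrum(hist)
      sim <- simulatePairGenotypes(lb, 1e5, spectrum = sp, seed = seed)
      jk <- jackknifeStats(perBlockCounts(sim$g1, sim$g2, sim$contig))
      exp <- pairStats(expectedCells(lb, sp))
      for (st in c("r0", "r1", "kingKinship")) {
        row <- jk[jk$statistic == st, ]
        expect_lt(abs(row$estimate - exp[[st]]),
                  max(3 * row$se, 0.01),
                  label = sprintf("%s/%s %s deviation", lb, hist, st))
      }
    }
  }
})
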