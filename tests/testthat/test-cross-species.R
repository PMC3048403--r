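test_that("percentile ranks follow the increasing-p sort with mean-rank ties", {
  set.seed(17)
  p <- runif(1000)
  names(p) <- sprintf("g%04d", seq_along(p))
  best <- names(p)[which.min(p)]
  expect_equal(percentileRank(p, best), 0.1)

  p200 <- sort(runif(200)); names(p200) <- sprintf("h%03d", 1:200)
  expect_equal(percentileRank(p200, "h003"), 1.5)

  # two genes tied at the 4th/5th smallest of 100 share the mean rank 4.5
  pt <- c(0.001, 0.002, 0.003, 0.01, 0.01, runif(95, 0.2, 1))
  names(pt) <- sprintf("t%03d", 1:100)
  expect_equal(percentileRank(pt, "t004"), 4.5)
  expect_equal(percentileRank(pt, "t005"), 4.5)

  # permutation invariance
  perm <- sample(seq_along(pt))
  expect_equal(percentileRank(pt[perm], "t004"), 4.5)

  expect_error(percentileRank(pt, "nope"), "absent from the platform")
})

test_that("binomial upper tail is exact and monotone", {
  expect_equal(binomialUpperTail(5, 0, 0.3), 1)
  expect_equal(binomialUpperTail(2, 2, 0.5), 0.25)
  expect_equal(binomialUpperTail(3, 2, 0.5), 0.5)
  expect_error(binomialUpperTail(3, 4, 0.5), "invalid")
  expect_error(binomialUpperTail(3, 2, 0), "invalid")

  for (n in c(4, 7, 9)) {
    for (p in c(0.1, 0.5, 0.85)) {
      tails <- vapply(0:n, function(k) binomialUpperTail(n, k, p), 0)
      brute <- vapply(0:n, function(k) bruteBinomialUpper(n, k, p), 0)
      expect_equal(tails, brute, tolerance = 1e-12)
      expect_true(all(diff(tails) <= 1e-12))  # non-increasing in k
    }
  }
  # non-decreasing in the null probability
  ps <- seq(0.05, 0.9, by = 0.05)
  expect_true(!is.unsorted(vapply(ps, function(p)
    binomialUpperTail(10, 4, p), 0)))
})

test_that("the archived two-platform comparison yields the printed concordant counts", {
  cmp <- readPlatformComparison(fixturePath("archived_human_platform.tsv"))
  ill <- summarizeOverlap(cmp$illumina, rankThreshold = 10)
  affy <- summarizeOverlap(cmp$affymetrix, rankThreshold = 10)
  expect_identical(ill$n, 22L)
  expect_identical(ill$k, 14L)
  expect_identical(affy$k, 13L)
  expect_true(all(ill$perGene$display[is.na(cmp$illumina$rank)] == "x"))
  expect_lt(ill$binomP, 1e-6)

  # direction checking: ITGB5 rises in the progression model but falls on
  # the reference platforms, so it drops out of k
  illDir <- summarizeOverlap(cmp$illumina, rankThreshold = 10,
                             checkDirection = TRUE)
  itgb5 <- illDir$perGene[illDir$perGene$gene == "ITGB5", ]
  expect_true(itgb5$significant)
  expect_false(itgb5$concordant)
  expect_lt(illDir$k, ill$k)
})

test_that("absent genes stay in n but never count as concordant", {
  gs <- data.frame(gene = c("A", "B", "C"), rank = c(NA, NA, NA),
                   fold = NA_real_, p = NA_real_)
  s <- summarizeOverlap(gs)
  expect_identical(s$k, 0L + 0L)
  expect_identical(s$n, 3L)
  expect_equal(s$binomP, 1)
  expect_error(summarizeOverlap(gs[0, ]), "empty gene list")
})

test_that("platform scoring finds genes case-insensitively and flags absences", {
  platform <- data.frame(gene = c("ACTA2", "VCL", "GSN"),
                         p = c(1e-5, 0.2, 0.5), fold = c(-3, -1.5, 2))
  st <- scorePlatform(c("Acta2", "Missing1"), platform,
                      mouseDirections = c(-1, -1))
  expect_equal(st$rank[1], 100 / 3)
  expect_true(is.na(st$rank[2]))
  s <- summarizeOverlap(st, rankThreshold = 40)
  expect_identical(s$perGene$display[2], "x")
})

test_that("simulated platforms plant the requested concordance", {
  genes <- sprintf("Mg%03d", 1:30)
  dirs <- rep(c(1, -1), 15)

  cfgAll <- simulationConfig(nProbes = 10, platformSize = 2000,
                             concordantFraction = 1, seed = 5)
  plat <- simulatePlatform(cfgAll, genes, dirs)
  st <- scorePlatform(genes, plat, dirs)
  s <- summarizeOverlap(st, rankThreshold = 10, checkDirection = TRUE)
  expect_identical(s$k, s$n)  # every gene concordant, direction included

  # zero planted concordance: significance arises by chance at ~pNull
  ks <- vapply(1:60, function(seed) {
    cfg0 <- simulationConfig(nProbes = 10, platformSize = 2000,
                             concordantFraction = 0, seed = seed)
    p0 <- simulatePlatform(cfg0, genes, dirs)
    summarizeOverlap(scorePlatform(genes, p0, dirs), rankThreshold = 10)$k
  }, 0L)
  expect_lt(abs(mean(ks) - 3), 1)  # E[k] = 0.1 * 30

  # determinism under a fixed seed
  expect_identical(simulatePlatform(cfgAll, genes, dirs),
                   simulatePlatform(cfgAll, genes, dirs))
})
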