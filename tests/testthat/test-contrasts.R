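test_that("signed fold change follows the published-table convention", {
  expect_equal(signedFoldChange(400, 400), 1)
  expect_equal(signedFoldChange(800, 400), 2)
  expect_equal(signedFoldChange(100, 400), -4)
  expect_error(signedFoldChange(0, 400), "positive")

  # antisymmetry: swapping arguments flips the sign, keeps the magnitude
  set.seed(5)
  a <- runif(50, 1, 1000); b <- runif(50, 1, 1000)
  f1 <- signedFoldChange(a, b); f2 <- signedFoldChange(b, a)
  uneq <- a != b
  expect_equal(abs(f1[uneq]), abs(f2[uneq]))
  expect_true(all(sign(f1[uneq]) == -sign(f2[uneq])))
  expect_true(all(abs(f1) >= 1))
})

test_that("two-sample t-test handles the pooled formula and degenerate variance", {
  expect_equal(tTestTwoSample(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(tTestTwoSample(1, c(1, 2)), "at least 2")

  # pooled-formula oracle computed directly from the t distribution
  a <- c(100, 110, 90); b <- c(200, 210, 190)
  s2 <- (var(a) * 2 + var(b) * 2) / 4
  tstat <- (mean(a) - mean(b)) / sqrt(s2 * (2 / 3))
  expect_equal(abs(tstat), 12.2474487, tolerance = 1e-6)
  expect_equal(tTestTwoSample(a, b), 2 * pt(-abs(tstat), df = 4))
  expect_lt(tTestTwoSample(a, b), 3e-4)

  # zero pooled variance: deterministic outcomes
  expect_equal(tTestTwoSample(c(5, 5), c(5, 5)), 1)
  expect_equal(tTestTwoSample(c(5, 5), c(7, 7)), 0)
})

test_that("vectorized per-probe contrasts match stats::t.test", {
  set.seed(21)
  se <- makeStageSet(matrix(rlnorm(20 * 9, 6, 0.6), nrow = 20))
  v <- intensities(se)
  for (variant in c("pooled", "welch")) {
    cs <- contrastStats(se, variant = variant)
    ref <- vapply(seq_len(20), function(i)
      t.test(v[i, 7:9], v[i, 1:3],
             var.equal = (variant == "pooled"))$p.value, 0)
    expect_equal(cs$p_LE, ref, tolerance = 1e-12)
    refIL <- vapply(seq_len(20), function(i)
      t.test(v[i, 7:9], v[i, 4:6],
             var.equal = (variant == "pooled"))$p.value, 0)
    expect_equal(cs$p_IL, refIL, tolerance = 1e-12)
  }
  cs <- contrastStats(se)
  expect_equal(cs$fc_LE,
               unname(signedFoldChange(rowMeans(v[, 7:9]),
                                       rowMeans(v[, 1:3]))))
  expect_equal(cs$max_intensity, unname(apply(v, 1, max)))
})

test_that("degenerate-variance probes get the deterministic convention", {
  v <- rbind(p1 = c(100, 100, 100, 100, 100, 100, 400, 400, 400),
             p2 = rep(7, 9))
  cs <- contrastStats(makeStageSet(v, probeIds = rownames(v)))
  expect_equal(cs$fc_IE, c(1, 1))
  expect_equal(cs$p_IE, c(1, 1))
  expect_equal(cs$fc_LE[1], 4)
  expect_equal(cs$p_LE, c(0, 1))
})

test_that("contrasts require every stage", {
  v <- matrix(rlnorm(12, 5, 1), 2,
              dimnames = list(c("a", "b"), paste0(rep(c("E", "I"), each = 3), 1:3)))
  se <- StageExpressionSet(v, stage = rep(c("E", "I"), each = 3),
                           replicate = rep(1:3, 2))
  expect_error(contrastStats(se), "missing stage 'L'")
})

test_that("a planted 4-fold late effect is detected across seeded draws", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    sdlog <- sqrt(log1p(0.05^2))
    vals <- c(rlnorm(6, log(500), sdlog), rlnorm(3, log(2000), sdlog))
    cs <- contrastStats(makeStageSet(matrix(vals, nrow = 1)))
    if (abs(cs$fc_LE) >= 3 && abs(cs$fc_LE) <= 5 && cs$p_LE < 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("the DE filter applies floor, fold and significance with stated boundaries", {
  cs <- data.frame(
    probe_id = c("floorFail", "downBoundary", "foldFail", "clearUp"),
    fc_IE = 1, p_IE = 0.5,
    fc_LE = c(10, -2.0, 1.9, 4), p_LE = c(0.001, 0.05, 0.001, 0.01),
    fc_IL = 1, p_IL = 0.5,
    max_intensity = c(499, 600, 600, 900))
  de <- deFilter(cs)
  expect_identical(de$down$probe_id, "downBoundary")  # thresholds inclusive
  expect_identical(de$up$probe_id, "clearUp")
  expect_setequal(de$excluded$probe_id, c("floorFail", "foldFail"))
  # exhaustive, disjoint partition
  expect_identical(nrow(de$up) + nrow(de$down) + nrow(de$excluded), nrow(cs))

  set.seed(8)
  rnd <- data.frame(probe_id = sprintf("r%d", 1:200),
                    fc_IE = 1, p_IE = 1,
                    fc_LE = sample(c(-1, 1), 200, TRUE) * runif(200, 1, 6),
                    p_LE = runif(200), fc_IL = 1, p_IL = 1,
                    max_intensity = runif(200, 100, 2000))
  deR <- deFilter(rnd)
  expect_identical(nrow(deR$up) + nrow(deR$down) + nrow(deR$excluded), 200L)
  expect_length(intersect(deR$up$probe_id, deR$down$probe_id), 0)
})

test_that("probe lists collapse to per-direction gene lists", {
  de <- list(up = data.frame(probe_id = c("a1", "a2", "b1")),
             down = data.frame(probe_id = c("c1", "b2", "x1")))
  map <- data.frame(probe_id = c("a1", "a2", "b1", "b2", "c1"),
                    gene = c("Acta2", "Acta2", "Gsn", "Gsn", "Vcl"))
  expect_warning(g <- collapseToGenes(de, map), "both directions")
  expect_setequal(g$up, c("Acta2", "Gsn"))
  expect_setequal(g$down, c("Vcl", "Gsn"))
  expect_identical(g$shared, "Gsn")
  expect_identical(g$unannotated, "x1")
})
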