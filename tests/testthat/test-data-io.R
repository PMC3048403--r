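test_that("expression tables round-trip with identical values and labels", {
  set.seed(7)
  values <- matrix(round(runif(27, 10, 2000), 3), nrow = 3,
                   dimnames = list(c("pA", "pB", "pC"), NULL))
  se <- makeStageSet(values, probeIds = rownames(values))
  tf <- tempfile(fileext = ".tsv")
  writeExpressionTable(se, tf)
  back <- readExpressionTable(tf, stageAssignment9())
  expect_s4_class(back, "StageExpressionSet")
  expect_identical(dim(back), c(3L, 9L))
  expect_equal(intensities(back), intensities(se))
  expect_identical(probeIds(back), probeIds(se))
  expect_identical(as.character(stages(back)), as.character(stages(se)))
  expect_identical(replicates(back), replicates(se))
})

test_that("malformed expression tables fail with informative errors", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("probe\tE1\tE2", "A\t1\t2", "A\t3\t4"), tf)
  sa <- data.frame(sample_id = c("E1", "E2"), stage = "E", replicate = 1:2)
  expect_error(readExpressionTable(tf, sa), "duplicate probe id: 'A'")

  writeLines(c("probe\tE1\tE2", "A\t1\t2", "B\t3\t4"), tf)
  expect_error(
    readExpressionTable(tf, data.frame(sample_id = "E1", stage = "E",
                                       replicate = 1)),
    "sample 'E2' has no stage assignment")

  writeLines(c("probe\tE1\tE2", "A\t1\toops", "B\t3\t4"), tf)
  expect_error(readExpressionTable(tf, sa), "non-numeric value 'oops'")
  expect_error(readExpressionTable(tf, sa), "probe 'A'.*sample 'E2'")
})

test_that("stage container enforces its invariants", {
  v <- matrix(1, 2, 9, dimnames = list(c("a", "b"), NULL))
  expect_error(StageExpressionSet(v, stage = rep("Q", 9), replicate = 1:9),
               "stage labels")
  expect_error(
    StageExpressionSet(v, stage = rep(c("E", "I", "L"), each = 3),
                       replicate = rep(1, 9)),
    "unique")
  v2 <- v; v2[1, 1] <- -5
  expect_error(
    StageExpressionSet(v2, stage = rep(c("E", "I", "L"), each = 3),
                       replicate = rep(1:3, 3)),
    "non-negative")
})

test_that("series-matrix dialect reads like the bare table with metadata stripped", {
  sa <- stageAssignment9()
  ids <- sa$sample_id
  dataRows <- c(paste(c("ID_REF", ids), collapse = "\t"),
                paste(c("\"1415670_at\"", 1:9 * 100), collapse = "\t"),
                paste(c("\"1415671_at\"", 1:9 * 10), collapse = "\t"))
  gf <- tempfile(fileext = ".txt")
  writeLines(c("!Series_title\t\"progression study\"",
               "!Series_platform_id\t\"GPL1261\"",
               "!Sample_count\t9",
               "!Series_summary\t\"three stages\"",
               "!Series_type\t\"Expression profiling by array\"",
               "!series_matrix_table_begin",
               dataRows,
               "!series_matrix_table_end"), gf)
  se <- readSeriesMatrix(gf, sa)
  expect_identical(dim(se), c(2L, 9L))
  # quotes stripped from identifiers
  expect_identical(probeIds(se), c("1415670_at", "1415671_at"))

  tf <- tempfile(fileext = ".tsv")
  writeLines(gsub('"', "", dataRows), tf)
  plain <- readExpressionTable(tf, sa)
  expect_equal(intensities(se), intensities(plain))

  # degenerate: metadata only
  mf <- tempfile()
  writeLines(c("!Series_title\t\"x\"", "!Series_type\t\"y\""), mf)
  expect_error(readSeriesMatrix(mf, sa), "no data table")

  # ragged body
  rf <- tempfile()
  writeLines(c("!series_matrix_table_begin", dataRows[1],
               "p1\t1\t2", "!series_matrix_table_end"), rf)
  expect_error(readSeriesMatrix(rf, sa), "ragged")
})

test_that("GMT gene sets parse, collapse duplicates and reject short lines", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("CYTOSKELETON\tdesc\tActa2\tVcl",
               "DUPES\tdesc2\tGsn\tGsn\tPxn"), gmt)
  expect_warning(sets <- readGeneSets(gmt), "duplicate members")
  expect_identical(sets$CYTOSKELETON, c("Acta2", "Vcl"))
  expect_identical(sort(sets$DUPES), c("Gsn", "Pxn"))
  expect_identical(attr(sets, "descriptions")[["DUPES"]], "desc2")

  writeLines(c("OK\td\tA", "BAD\tonlydesc"), gmt)
  expect_error(readGeneSets(gmt), "line 2")
})

test_that("GMT parsing agrees with an independent reader", {
  skip_if_not_installed("fgsea")
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tfirst\tActa2\tVcl\tGsn",
               "S2\tsecond\tPxn\tZyx"), gmt)
  ours <- readGeneSets(gmt)
  theirs <- fgsea::gmtPathways(gmt)
  expect_identical(names(ours), names(theirs))
  for (s in names(ours)) expect_identical(ours[[s]], theirs[[s]])
})

test_that("results tables render published-table conventions and round-trip", {
  rec <- data.frame(gene = "Acta2", accession = "NM_007392",
                    fc_IE = -2.8, p_IE = 0.0698,
                    fc_LE = -19.3, p_LE = 0.0139, trajectory = "late_down")
  tf <- tempfile(fileext = ".tsv")
  writeResultsTable(rec, tf)
  lines <- readLines(tf)
  expect_identical(
    lines[2],
    "Acta2\tNM_007392\t-2.8\t0.0698\t-19.3\t0.0139\tlate_down")

  back <- readResultsTable(tf)
  expect_equal(back$fc_LE, -19.3)
  expect_equal(back$p_IE, 0.0698)

  # arbitrary numerics reproduce at rendered precision
  set.seed(42)
  fc <- round(runif(5, 1.05, 60), 3) * sample(c(-1, 1), 5, TRUE)
  p <- round(runif(5), 5)
  rec2 <- data.frame(gene = letters[1:5], fc_IE = fc, p_IE = p,
                     fc_LE = rev(fc), p_LE = rev(p))
  writeResultsTable(rec2, tf)
  back2 <- readResultsTable(tf)
  expect_equal(back2$fc_IE, as.numeric(sprintf("%.1f", fc)))
  expect_equal(back2$p_LE, as.numeric(sprintf("%.4f", rev(p))))

  # empty record list -> header only
  writeResultsTable(data.frame(), tf)
  expect_length(readLines(tf), 1L)
})
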