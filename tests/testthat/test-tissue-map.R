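test_that("patch sampling draws max(1, round(ratio * N)) distinct positions", {
  expect_equal(nrow(samplePatches(c(10L, 10L), samplingConfig(0.05, 1))), 5L)
  expect_equal(nrow(samplePatches(c(1L, 1L), samplingConfig(0.01, 1))), 1L)

  for (N in c(1L, 7L, 50L, 313L, 10000L)) {
    nr <- max(1L, N %/% 10L); nc <- ceiling(N / nr)
    avail <- matrix(FALSE, nr, nc); avail[seq_len(N)] <- TRUE
    for (ratio in c(0.01, 0.05, 0.5, 1.0)) {
      got <- samplePatches(avail, samplingConfig(ratio, seed = 3))
      expect_equal(nrow(got), max(1L, min(N, floor(ratio * N + 0.5))))
      expect_equal(anyDuplicated(paste(got$row, got$col)), 0L)
    }
  }

  a <- samplePatches(c(25L, 40L), samplingConfig(0.05, seed = 11))
  b <- samplePatches(c(25L, 40L), samplingConfig(0.05, seed = 11))
  expect_identical(a, b)

  expect_error(samplePatches(matrix(FALSE, 2, 2), samplingConfig(0.5)),
               "empty")
  expect_error(samplingConfig(0), "\\(0, 1\\]")
})

test_that("majority label picks the largest class, ties by enum order", {
  expect_equal(majorityLabel(rep("TUM", 10)), "TUM")
  expect_equal(majorityLabel(c(rep("STR", 6), rep("TUM", 4))), "STR")
  # 50/50 tie: LYM precedes TUM in the enumeration
  expect_equal(majorityLabel(c("TUM", "LYM")), "LYM")
  expect_equal(majorityLabel(c(TUM = 0.5, LYM = 0.5)), "LYM")
  expect_error(majorityLabel(character(0)), "empty")
  expect_error(majorityLabel("NOPE"), "invalid")
})

test_that("trained classifier exceeds 90% held-out accuracy on textures", {
  classes <- tissueClasses()
  train <- list(); trainLab <- character()
  test <- list(); testLab <- character()
  for (i in seq_along(classes)) {
    tr <- generatePatchImages(classes[i], 80, edge = 16, seed = 100 + i)
    te <- generatePatchImages(classes[i], 40, edge = 16, seed = 200 + i)
    train <- c(train, tr); trainLab <- c(trainLab, rep(classes[i], 80))
    test <- c(test, te); testLab <- c(testLab, rep(classes[i], 40))
  }
  clf <- trainPatchClassifier(train, trainLab, seed = 7)
  pred <- classifyPatches(clf, test)
  expect_gt(mean(pred$class == testLab), 0.9)
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))

  expect_error(trainPatchClassifier(list(), character(0)), "empty")
  expect_error(trainPatchClassifier(train[1:5], rep("TUM", 5)),
               "two classes")
})

test_that("oracle classification reproduces ground truth cell-for-cell", {
  g <- generateTissueMap(syntheticCohortConfig(n_patients = 1, seed = 21), 1)
  clf <- oracleClassifier(g$map)
  d <- dim(g$map)
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  tm <- buildTissueMap(grid, d[1], d[2], clf, slideID = "s1")
  expect_identical(as.matrix(tm), as.matrix(g$map))

  # oracle accuracy 1.0 on sampled positions
  pos <- samplePatches(g$map, samplingConfig(0.1, seed = 2))
  pred <- classifyPatches(clf, pos)
  expect_equal(pred$class, as.matrix(g$map)[cbind(pos$row, pos$col)])
  expect_true(all(pred$confidence == 1))

  # incomplete grid errors with the offending position
  expect_error(buildTissueMap(grid[-5, ], d[1], d[2], clf), "5,1")
})

test_that("superclass collapse preserves shape and cell counts", {
  lab <- matrix(c("TUM", "MUC", "STR", "LYM", "BACK", "NORM"), 2, 3)
  tm <- TissueMap(lab, slideID = "x", patchSize = 224L)
  sup <- toSuperclass(tm)
  expect_equal(dim(sup), dim(tm))
  sm <- as.matrix(sup)
  expect_equal(sm[1, 1], "tumor")
  expect_equal(sm[2, 1], "other")   # MUC maps to other
  expect_equal(sm[1, 2], "stroma")
  expect_equal(sm[2, 2], "lymphocyte")
  expect_equal(sm[1, 3], "other")   # BACK

  set.seed(31)
  m <- matrix(sample(tissueClasses(), 9, replace = TRUE), 3, 3)
  counts <- tissueCounts(m)
  sc <- tissueCounts(toSuperclass(m), classSet = superClasses())
  expect_equal(sum(sc), sum(counts))
  expect_equal(unname(sc["tumor"]), unname(counts["TUM"]))
  expect_equal(unname(sc["other"]),
               sum(counts[c("ADI", "BACK", "DEB", "MUC", "MUS", "NORM")]))
})

test_that("tissue maps round-trip through CSV and PNG", {
  g <- generateTissueMap(syntheticCohortConfig(n_patients = 1, seed = 8), 1)
  tf <- tempfile(fileext = ".csv")
  writeTissueMapCSV(g$map, tf, configHash = "abc123")
  back <- readTissueMapCSV(tf)
  expect_identical(as.matrix(back), as.matrix(g$map))
  expect_equal(slideID(back), slideID(g$map))
  expect_match(readLines(tf, n = 1), "config_hash=abc123")

  tp <- tempfile(fileext = ".png")
  writeTissueMapPNG(g$map, tp)
  back2 <- readTissueMapPNG(tp, slideID = slideID(g$map))
  expect_identical(as.matrix(back2), as.matrix(g$map))
})

test_that("TissueMap validity rejects bad labels", {
  expect_error(TissueMap(matrix("??", 2, 2)), "invalid labels")
  tm <- TissueMap(matrix("TUM", 2, 2))
  expect_equal(dim(tm), c(2L, 2L))
  expect_output(show(tm), "TissueMap")
})
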