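test_that("planted blobs appear in the map with exact recountable truth", {
  # degenerate single-cell blob
  g0 <- generateTissueMap(fixedBlobConfig(0, lym_inside_rate = 0,
                                          lym_around_rate = 0,
                                          stroma_fraction = 0), 1)
  expect_equal(sum(as.matrix(g0$map) == "TUM"), 1L)
  expect_equal(g0$truth$max_tumor_area, 1L)

  # square blob of side 5: recount equals planted area 25
  g2 <- generateTissueMap(fixedBlobConfig(2, lym_inside_rate = 0,
                                          lym_around_rate = 0), 1)
  expect_equal(sum(as.matrix(g2$map) == "TUM"), 25L)
  expect_equal(g2$truth$max_tumor_area, 25L)

  # zero lymphocyte rates: no LYM anywhere
  expect_equal(g2$truth$lymphocyte_inside_tumor, 0L)
  expect_equal(g2$truth$lymphocyte_around_tumor, 0L)
  expect_equal(sum(as.matrix(g2$map) == "LYM"), 0L)

  # out-of-bounds blob is a configuration error
  bad <- syntheticCohortConfig(n_patients = 1, map_rows = 10, map_cols = 10,
    tumor_blobs = list(list(row = 1L, col = 5L, radius = 3L)))
  expect_error(generateTissueMap(bad, 1), "out of grid bounds")
  expect_error(generateTissueMap(fixedBlobConfig(2), 5), "out of range")
})

test_that("ground-truth counts equal direct recounts for every seed", {
  for (s in 1:12) {
    cfg <- syntheticCohortConfig(n_patients = 2, seed = s)
    for (p in 1:2) {
      g <- generateTissueMap(cfg, p)
      m <- as.matrix(g$map)
      expect_equal(sum(m == "TUM"), g$truth$tum_cells)
      expect_equal(sum(m == "LYM"), g$truth$lym_cells)
      expect_equal(sum(m == "STR"), g$truth$str_cells)
      expect_equal(g$truth$lym_cells,
                   g$truth$lymphocyte_inside_tumor +
                     g$truth$lymphocyte_around_tumor)
      expect_equal(g$truth$around_inside_ratio,
                   (g$truth$lymphocyte_around_tumor + 1) /
                     (g$truth$lymphocyte_inside_tumor + 1))
    }
  }
})

test_that("generators are bit-identical under identical seeds", {
  cfg <- syntheticCohortConfig(n_patients = 3, seed = 99)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(lapply(tissueMaps(a), as.matrix),
                   lapply(tissueMaps(b), as.matrix))
  expect_identical(survivalData(a), survivalData(b))

  p1 <- generatePatchImages("TUM", 3, 32, seed = 1)
  p2 <- generatePatchImages("TUM", 3, 32, seed = 1)
  expect_identical(p1, p2)
})

test_that("patch textures are class-separable and correctly shaped", {
  one <- generatePatchImages("LYM", 1, edge = 16, seed = 2)
  expect_length(one, 1L)
  expect_equal(dim(one[[1]]), c(16, 16, 3))
  expect_true(all(one[[1]] >= 0 & one[[1]] <= 1))

  tum <- generatePatchImages("TUM", 100, edge = 16, seed = 3)
  lym <- generatePatchImages("LYM", 100, edge = 16, seed = 4)
  mTum <- colMeans(t(vapply(tum, function(x) apply(x, 3, mean), numeric(3))))
  mLym <- colMeans(t(vapply(lym, function(x) apply(x, 3, mean), numeric(3))))
  noise <- sd(vapply(tum, function(x) mean(x[, , 1]), numeric(1)))
  # class mean separation exceeds the within-class noise scale
  expect_gt(max(abs(mTum - mLym)), 5 * noise)

  expect_error(generatePatchImages("XXX", 1), "unknown tissue class")
  expect_error(generatePatchImages("TUM", 0), ">= 1")
})

test_that("survival generation follows the proportional-hazards contract", {
  cfg <- syntheticCohortConfig(n_patients = 200, seed = 3)
  maps <- lapply(1:200, function(i) generateTissueMap(cfg, i))
  truth <- do.call(rbind, lapply(maps, `[[`, "truth"))

  # betas = 0, censor = 0: all events observed
  s0 <- generateSurvival(truth, rep(0, 5), 0, seed = 1)
  expect_true(all(s0$event == 1L))
  expect_true(all(s0$log_hazard == 0))

  # censor_rate = 1: everyone censored
  s1 <- generateSurvival(truth, rep(0, 5), 1, seed = 1)
  expect_true(all(s1$event == 0L))

  # realized censoring near the target
  s2 <- generateSurvival(truth, cfg$hazard_betas, 0.3, seed = 2)
  expect_lt(abs(mean(1 - s2$event) - 0.3), 0.05)

  # strong positive tumor-area effect: bigger tumors die sooner
  s3 <- generateSurvival(truth, c(2, 0, 0, 0, 0), 0, seed = 3)
  expect_lt(cor(truth$max_tumor_area, s3$time, method = "spearman"), 0)

  expect_error(generateSurvival(truth, rep(0, 5), 1.5), "censor_rate")
  expect_error(generateSurvival(truth, c(Inf, 0, 0, 0, 0), 0), "finite")
})

test_that("configuration invariants are enforced", {
  expect_error(syntheticCohortConfig(lym_inside_rate = 1.2), "\\[0, 1\\]")
  expect_error(syntheticCohortConfig(map_rows = 6, radius_range = c(4, 5)),
               "twice")
  expect_error(syntheticCohortConfig(hazard_betas = 1:3), "5 finite")
})
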