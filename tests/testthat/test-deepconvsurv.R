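test_that("Cox partial likelihood matches hand computations", {
  # single subject with an event: r - log exp(r) = 0
  expect_equal(coxPartialNLL(0.7, 1, 1), 0)
  # two subjects, equal risks, both events, distinct times:
  # terms are -log 2 and 0, averaged over the 2 events
  expect_equal(coxPartialNLL(c(1, 1), c(1, 2), c(1, 1)), log(2) / 2)
  expect_error(coxPartialNLL(c(0, 0), c(1, 2), c(0, 0)), "event")

  # Breslow tie handling: both tied events see the full risk set
  r <- c(0.3, -0.2, 0.5)
  byHand <- -((r[1] - log(sum(exp(r)))) + (r[2] - log(sum(exp(r))))) / 2
  expect_equal(coxPartialNLL(r, c(1, 1, 2), c(1, 1, 0)), byHand)
})

test_that("analytic Cox gradient matches central finite differences", {
  set.seed(41)
  for (r in 1:25) {
    n <- sample(4:12, 1)
    risks <- rnorm(n); times <- rexp(n) + 0.05
    events <- rbinom(n, 1, 0.6)
    if (sum(events) == 0) events[sample(n, 1)] <- 1L
    g <- coxPartialNLLGrad(risks, times, events)
    fd <- vapply(seq_len(n), function(k) {
      e <- 1e-5
      up <- risks; up[k] <- up[k] + e
      dn <- risks; dn[k] <- dn[k] - e
      (coxPartialNLL(up, times, events) -
         coxPartialNLL(dn, times, events)) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(g - fd)), 1e-5)
  }
})

test_that("extractor training is seeded, event-guarded and improves on signal", {
  set.seed(43)
  n <- 60
  lp <- rnorm(n)
  imgs <- lapply(seq_len(n), function(i)
    generatePatchImages("TUM", 1, 16, seed = 3000 + i,
                        intensity = 0.15 * lp[i])[[1]])
  times <- rexp(n) / exp(lp)
  cfg <- deepConvSurvConfig(edge = 16L, convFilters = c(6L, 12L),
                            epochs = 6L, lr = 2e-3, batch = 20L, seed = 5L)

  expect_error(trainTissueExtractor(imgs, times, rep(0L, n), cfg),
               "all-censored")
  expect_error(trainTissueExtractor(imgs, times, rep(1L, n), cfg,
                                    patient_id = rep("P1", n)),
               "two distinct patients")

  ext <- trainTissueExtractor(imgs, times, rep(1L, n), cfg)
  # loss after training does not exceed the first-epoch loss
  expect_lte(ext@trace[length(ext@trace)], ext@trace[1])

  # bit-identical weights under the same seed
  ext2 <- trainTissueExtractor(imgs, times, rep(1L, n), cfg)
  expect_identical(ext@params, ext2@params)

  # held-out risks track the planted hazard
  lpTe <- rnorm(30)
  te <- lapply(seq_len(30), function(i)
    generatePatchImages("TUM", 1, 16, seed = 9000 + i,
                        intensity = 0.15 * lpTe[i])[[1]])
  expect_gt(cor(predictRisk(ext, te), lpTe, method = "spearman"), 0)

  f <- patchFeatures(ext, te)
  expect_equal(dim(f), c(30L, 32L))
  expect_true(all(is.finite(f)))
})

test_that("per-tissue aggregation applies the patch-share weight", {
  expect_equal(aggregateTissue(matrix(1, 10, 32), 10, 40),
               rep(0.25, 32))
  expect_equal(aggregateTissue(NULL, 0, 40), numeric(32))
  f <- matrix(rnorm(5 * 32), 5, 32)
  expect_equal(aggregateTissue(f, 5, 5), colMeans(f))
  expect_error(aggregateTissue(f, 5, 0), "positive")
  expect_error(aggregateTissue(f, 6, 5), "exceed")

  # permutation invariance over patches
  perm <- sample(5)
  expect_equal(aggregateTissue(f[perm, ], 5, 9),
               aggregateTissue(f, 5, 9))
})

test_that("tissue weights sum to one exactly when the set covers all patches", {
  counts <- c(TUM = 12L, LYM = 5L, STR = 8L, MUC = 3L)
  nTotal <- sum(counts)
  w <- counts / nTotal
  expect_equal(sum(w), 1)
  expect_lt(sum(w[c("TUM", "LYM")]), 1)
})

test_that("histopathological concatenation has fixed order and width", {
  vecs <- list(TUM = rep(1, 32), LYM = rep(2, 32), STR = rep(3, 32),
               MUC = rep(4, 32))
  h <- concatHisto(vecs)
  expect_length(h, 128L)
  expect_equal(unname(h[1:32]), rep(1, 32))
  expect_equal(unname(h[97:128]), rep(4, 32))
  expect_equal(names(h)[33], "LYM_1")

  expect_equal(unname(concatHisto(lapply(vecs, function(x) x * 0))),
               rep(0, 128))
  bad <- vecs; bad$MUC <- rep(4, 16)
  expect_error(concatHisto(bad), "widths differ")
  expect_error(concatHisto(vecs[1:3]), "missing tissue")

  # width scales with the tissue subset
  expect_length(concatHisto(vecs, tissues = c("TUM", "STR")), 64L)
  expect_length(concatHisto(vecs["TUM"], tissues = "TUM"), 32L)
})

test_that("combination search enumerates every non-empty subset", {
  expect_length(tissueCombinations(setdiff(tissueClasses(), "BACK")), 255L)
  expect_length(tissueCombinations(c("TUM", "LYM")), 3L)
  expect_error(tissueCombinations(c("TUM", "BACK")), "BACK")

  set.seed(47)
  n <- 60
  feats <- list(TUM = matrix(rnorm(n * 4), n), LYM = matrix(rnorm(n * 4), n))
  rec <- makeRecords(n)
  res <- tissueCombinationSearch(feats, rec,
    evalFun = function(X, records) c(stub = ncol(X)))
  expect_equal(nrow(res), 3L)
  expect_setequal(res$subset, c("TUM", "LYM", "TUM+LYM"))
})

test_that("the search ranks signal-bearing tissues first", {
  set.seed(53)
  n <- 90
  lp <- rnorm(n)
  rec <- makeRecords(n, lp = lp, censor = 0.1, seed = 54)
  feats <- list(
    TUM = cbind(lp + rnorm(n, sd = 0.2), matrix(rnorm(n * 3), n)),
    LYM = matrix(rnorm(n * 4), n),
    STR = matrix(rnorm(n * 4), n))
  res <- tissueCombinationSearch(feats, rec, models = "ridge_cox", k = 3,
                                 seed = 2)
  expect_equal(nrow(res), 7L)
  best <- res$subset[which.max(res$mean_cindex)]
  expect_match(best, "TUM")
})
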