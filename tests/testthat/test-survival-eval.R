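test_that("concordance index implements the literal pairwise definition", {
  expect_equal(concordanceIndex(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1.0)
  expect_equal(concordanceIndex(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3)), 0.0)
  expect_equal(concordanceIndex(c(1, 2, 3, 4), c(1, 1, 1, 1), c(4, 3, 1, 2)),
               5 / 6)
  expect_error(concordanceIndex(c(1, 1), c(0, 1), c(1, 2)), "comparable")

  # tied risks: no credit by default, half credit under Harrell
  expect_equal(concordanceIndex(c(1, 2), c(1, 1), c(5, 5)), 0)
  expect_equal(concordanceIndex(c(1, 2), c(1, 1), c(5, 5), ties = "harrell"),
               0.5)
})

test_that("concordance index agrees with the double-loop oracle", {
  set.seed(59)
  for (r in 1:60) {
    n <- sample(5:30, 1)
    times <- round(rexp(n), 2) + 0.01  # induce occasional time ties
    events <- rbinom(n, 1, 0.7)
    risks <- sample(seq_len(5), n, replace = TRUE) + rnorm(n, sd = 0.01)
    if (r %% 3 == 0) risks <- sample(seq_len(3), n, replace = TRUE)
    ok <- tryCatch({
      want <- oracleCIndex(times, events, risks)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    expect_equal(concordanceIndex(times, events, risks), want)
    expect_equal(concordanceIndex(times, events, risks, ties = "harrell"),
                 oracleCIndex(times, events, risks, harrell = TRUE))
  }
})

test_that("reversing risks maps C to 1 - C on tie-free uncensored data", {
  set.seed(61)
  for (r in 1:10) {
    n <- 20
    times <- rexp(n); risks <- rnorm(n)
    ci <- concordanceIndex(times, rep(1, n), risks)
    expect_equal(concordanceIndex(times, rep(1, n), -risks), 1 - ci)
    expect_true(ci >= 0 && ci <= 1)
  }
})

test_that("Kaplan-Meier is the product-limit estimator", {
  km0 <- kaplanMeier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  km <- kaplanMeier(c(1, 2), c(1, 1))
  expect_equal(kmSurvival(km, c(0.5, 1, 1.5, 2)), c(1, 0.5, 0.5, 0))

  # duplicating every record leaves the curve unchanged
  set.seed(67)
  t1 <- rexp(25); e1 <- rbinom(25, 1, 0.7)
  a <- kaplanMeier(t1, e1)
  b <- kaplanMeier(c(t1, t1), c(e1, e1))
  expect_equal(kmSurvival(b, a$time), a$surv)

  # cross-check against the survival package
  skip_if_not_installed("survival")
  sf <- survival::survfit(survival::Surv(t1, e1) ~ 1)
  expect_equal(kmSurvival(a, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("log-rank test matches the survival package and detects separation", {
  t1 <- rexp(40, 1); t2 <- rexp(40, 5)
  times <- c(t1, t2); events <- rep(1L, 80)
  grp <- rep(c("a", "b"), each = 40)

  # identical groups: statistic 0, p = 1
  same <- logrankTest(c(t1, t1), rep(1L, 80), grp)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  sep <- logrankTest(times, events, grp)
  expect_lt(sep$p.value, 0.01)

  expect_error(logrankTest(t1, rep(1L, 40), rep("a", 40)), "two")

  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  expect_equal(sep$statistic, sd$chisq, tolerance = 1e-8)
})

test_that("log-rank p-values are calibrated under the null", {
  set.seed(71)
  n <- 60
  times <- rexp(n); events <- rbinom(n, 1, 0.8)
  ps <- replicate(300, {
    logrankTest(times, events, sample(rep(c("a", "b"), each = n / 2)))$p.value
  })
  # roughly uniform: KS against U(0,1) should not reject hard
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("maxstat cutpoint equals the exhaustive-scan oracle", {
  expect_error(maxstatCutoff(rep(1, 10), rexp(10), rep(1, 10)), "constant")

  # two separated clusters with different survival: cutoff between clusters
  set.seed(73)
  x <- c(rnorm(30, 0, 0.3), rnorm(30, 5, 0.3))
  times <- c(rexp(30, 0.2), rexp(30, 3))
  res <- maxstatCutoff(x, times, rep(1L, 60), nperm = 200, seed = 1)
  expect_gt(res$cutoff, max(x[1:30]) - 1e-9)
  expect_lt(res$cutoff, min(x[31:60]))
  expect_lt(res$p.value, 0.05)

  for (r in 1:25) {
    n <- sample(20:60, 1)
    x <- rnorm(n); times <- rexp(n); events <- rbinom(n, 1, 0.8)
    if (sum(events) == 0) events[1] <- 1L
    got <- maxstatCutoff(x, times, events, nperm = 0)
    want <- oracleMaxstat(x, times, events)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$statistic, want$z, tolerance = 1e-10)
    # group sizes consistent with strict discretization
    expect_equal(sum(discretize(x, got$cutoff)), got$n.high)
  }

  # the only split (1 vs 9) violates the minimal group proportion
  expect_error(maxstatCutoff(c(1, rep(2, 9)), rexp(10), rep(1L, 10),
                             minprop = 0.3),
               "admissible")
})

test_that("discretization is strict and monotone", {
  expect_equal(discretize(5, 5), 0L)
  expect_equal(discretize(5 + 1e-12, 5), 1L)
  x <- sort(rnorm(20))
  d <- discretize(x, 0)
  expect_true(all(diff(d) >= 0))
})

test_that("feature merging yields the 133-wide vector in block order", {
  z <- mergeFeatures(numeric(128), numeric(5))
  expect_equal(dim(z), c(1L, 133L))
  expect_true(all(z == 0))

  h <- matrix(seq_len(128), 1)
  a <- matrix(c(1, 0, 1, 0, 1), 1)
  m <- mergeFeatures(h, a)
  expect_equal(unname(m[1, 1:128]), as.numeric(1:128))
  expect_equal(unname(m[1, 129:133]), c(1, 0, 1, 0, 1))
  expect_equal(colnames(m)[129], "max_tumor_area")

  expect_error(mergeFeatures(numeric(127), numeric(5)), "128")
  expect_error(mergeFeatures(numeric(128), numeric(4)), "5")
})

test_that("all six survival models fit and predict with risk orientation", {
  set.seed(79)
  n <- 120
  X <- matrix(rnorm(n * 8), n, 8)
  lp <- 1.3 * X[, 1]
  rec <- makeRecords(n, lp = lp, censor = 0.15, seed = 80)

  for (nm in survModels()) {
    fit <- fitSurvivalModel(nm, X, rec)
    r <- predictRisk(fit, X)
    expect_length(r, n)
    expect_true(all(is.finite(r)))
    # in-sample concordance above chance for a strong linear signal
    expect_gt(concordanceIndex(rec$time, rec$event, r, ties = "harrell"),
              0.6)
  }
  expect_error(fitSurvivalModel("coxboost", X, rec), "unknown")
  recBad <- rec; recBad$event <- 0L
  expect_error(fitSurvivalModel("ridge_cox", X, recBad), "no events")
})

test_that("cross-validation folds are disjoint, covering and seeded", {
  set.seed(83)
  n <- 100
  X <- matrix(rnorm(n * 6), n, 6)
  rec <- makeRecords(n, lp = X[, 1], censor = 0.2, seed = 84)
  cv <- crossValidate(X, rec, models = "ridge_cox", k = 5, seed = 9)
  fa <- attr(cv, "fold_assign")
  expect_equal(sort(unique(fa)), 1:5)
  expect_equal(length(fa), n)
  expect_true(all(table(fa) >= floor(n / 5) - 2))
  folds <- attr(cv, "folds")
  expect_equal(nrow(folds), 5L)
  expect_true(all(folds$cindex >= 0 & folds$cindex <= 1))

  cv2 <- crossValidate(X, rec, models = "ridge_cox", k = 5, seed = 9)
  expect_identical(cv, cv2)
})

test_that("training-fold cutpoints ignore test-fold data", {
  set.seed(89)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- c("a", "b", "c")
  rec <- makeRecords(n, lp = X[, 1], censor = 0.1, seed = 90)
  cv <- crossValidate(X, rec, models = "ridge_cox", k = 4, seed = 3,
                      discretizeCols = "a")
  fa <- attr(cv, "fold_assign")
  # inject an extreme outlier into a fold-2 test row only
  X2 <- X
  X2[which(fa == 2)[1], "a"] <- 1e6
  cv2 <- crossValidate(X2, rec, models = "ridge_cox", k = 4, seed = 3,
                       discretizeCols = "a")
  cuts1 <- attr(cv, "cutoffs"); cuts2 <- attr(cv2, "cutoffs")
  # every fold that trains without the outlier keeps its cutoff
  for (f in setdiff(1:4, 2)) {
    expect_identical(cuts1[[f]], cuts2[[f]])
  }
})

test_that("signal cohorts outperform matched noise cohorts", {
  set.seed(97)
  n <- 100
  Xs <- matrix(rnorm(n * 5), n, 5)
  recS <- makeRecords(n, lp = 1.5 * Xs[, 1], censor = 0.15, seed = 98)
  recN <- makeRecords(n, lp = rep(0, n), censor = 0.15, seed = 99)
  mods <- c("ridge_cox", "rsf")
  cvS <- crossValidate(Xs, recS, models = mods, k = 5, seed = 4)
  cvN <- crossValidate(Xs, recN, models = mods, k = 5, seed = 4)
  for (mm in mods) {
    expect_gt(cvS$mean_cindex[cvS$model == mm],
              cvN$mean_cindex[cvN$model == mm])
  }
})
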