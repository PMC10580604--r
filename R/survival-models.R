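# The six survival models behind a uniform fit/predictRisk surface.
# lasso_cox / ridge_cox / en_cox are penalized Cox models (glmnet);
# rsf is a random survival forest (ranger); gbrt is gradient boosted trees
# with the Cox objective (xgboost); ssvm is a linear ranking survival SVM
# (squared hinge on comparable pairs) implemented here. All predictions are
# oriented so that higher risk means worse predicted outcome.

#' Names of the supported survival models
#'
#' @return character vector of the six model names.
#' @export
survModels <- function() {
  c("lasso_cox", "ridge_cox", "en_cox", "ssvm", "rsf", "gbrt")
}

.checkRecords <- function(records, n) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  if (nrow(records) != n) stop("records and feature rows must align")
  if (any(records$time <= 0)) stop("times must be positive")
  if (sum(records$event) == 0L) stop("degenerate fold: no events")
  records
}

.fitGlmnetCox <- function(X, records, alpha, hyper) {
  y <- cbind(time = records$time, status = records$event)
  lambda <- hyper$lambda
  if (is.null(lambda)) {
    nfolds <- hyper$cv_nfolds %||% 3L
    foldid <- rep_len(seq_len(nfolds), nrow(X))[sample(nrow(X))]
    lambda <- tryCatch(
      glmnet::cv.glmnet(X, y, family = "cox", alpha = alpha,
                        foldid = foldid, grouped = TRUE)$lambda.min,
      error = function(e) 0.1)  # sparse-event folds: fixed moderate penalty
  }
  fit <- glmnet::glmnet(X, y, family = "cox", alpha = alpha)
  list(fit = fit, lambda = lambda)
}

.fitSSVM <- function(X, records, hyper) {
  # linear ranking SVM on comparable pairs (i uncensored, T_j > T_i must
  # rank i above j), squared hinge with L2 regularization, full-gradient
  # descent with a fixed step schedule
  reg <- hyper$reg %||% 0.1
  iters <- hyper$iters %||% 300L
  lr <- hyper$lr %||% 0.05
  n <- nrow(X)
  cmp <- outer(records$time, records$time, "<")
  cmp[records$event == 0, ] <- FALSE
  pairs <- which(cmp, arr.ind = TRUE)     # risk of [ ,1] should exceed [ ,2]
  if (nrow(pairs) == 0L) stop("no comparable pairs for ssvm")
  w <- numeric(ncol(X))
  for (it in seq_len(iters)) {
    s <- drop(X %*% w)
    marg <- 1 - (s[pairs[, 1]] - s[pairs[, 2]])
    act <- marg > 0
    g <- reg * w
    if (any(act)) {
      D <- X[pairs[act, 1], , drop = FALSE] - X[pairs[act, 2], , drop = FALSE]
      g <- g - 2 * colSums(marg[act] * D) / nrow(pairs)
    }
    w <- w - lr * g
  }
  w
}

#' Fit one of the six survival models
#'
#' Features are standardized internally (the stored center/scale are
#' reapplied at prediction time). Hyperparameters not supplied fall back to
#' fixed documented defaults.
#'
#' @param name one of [survModels()].
#' @param X numeric feature matrix (patients x features).
#' @param records data.frame with columns `time`, `event` aligned with `X`.
#' @param hyper named list of hyperparameter overrides: `lambda`,
#'   `cv_nfolds` (penalized Cox), `reg`, `iters`, `lr` (ssvm),
#'   `num_trees`, `mtry` (rsf), `nrounds`, `max_depth`, `eta` (gbrt).
#' @return a [SurvModel-class].
#' @export
fitSurvivalModel <- function(name, X, records, hyper = list()) {
  if (!name %in% survModels())
    stop(sprintf("unknown survival model '%s'", name))
  X <- as.matrix(X)
  records <- .checkRecords(records, nrow(X))
  if (nrow(X) < 4L) stop("too few patients to fit a survival model")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  colnames(Xs) <- sprintf("f%d", seq_len(ncol(Xs)))
  fit <- switch(name,
    lasso_cox = .fitGlmnetCox(Xs, records, alpha = 1, hyper),
    ridge_cox = .fitGlmnetCox(Xs, records, alpha = 0, hyper),
    en_cox = .fitGlmnetCox(Xs, records, alpha = hyper$alpha %||% 0.5, hyper),
    ssvm = .fitSSVM(Xs, records, hyper),
    rsf = {
      df <- data.frame(time = records$time, status = records$event, Xs)
      ranger::ranger(data = df, dependent.variable.name = "time",
                     status.variable.name = "status",
                     num.trees = hyper$num_trees %||% 300L,
                     mtry = hyper$mtry %||% max(1L, floor(sqrt(ncol(Xs)))),
                     min.node.size = hyper$min_node_size %||% 5L,
                     seed = hyper$seed %||% 1L, num.threads = 1L)
    },
    gbrt = {
      lab <- ifelse(records$event == 1, records$time, -records$time)
      dtr <- xgboost::xgb.DMatrix(Xs, label = lab)
      xgboost::xgb.train(params = list(objective = "survival:cox",
                                       eta = hyper$eta %||% 0.1,
                                       max_depth = hyper$max_depth %||% 2L,
                                       nthread = 1L),
                         data = dtr, nrounds = hyper$nrounds %||% 100L,
                         verbose = 0)
    })
  new("SurvModel", name = name, fit = fit, center = ctr, scale = scl,
      hyper = hyper)
}

#' @rdname predictRisk
#' @export
setMethod("predictRisk", "SurvModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- scale(X, center = object@center, scale = object@scale)
  colnames(Xs) <- sprintf("f%d", seq_len(ncol(Xs)))
  nm <- object@name
  if (nm %in% c("lasso_cox", "ridge_cox", "en_cox")) {
    drop(predict(object@fit$fit, newx = Xs, s = object@fit$lambda,
                 type = "link"))
  } else if (nm == "ssvm") {
    drop(Xs %*% object@fit)
  } else if (nm == "rsf") {
    pr <- predict(object@fit, data = data.frame(Xs), num.threads = 1L)
    rowSums(pr$chf)                       # ensemble mortality
  } else {                                # gbrt: hazard-ratio predictions
    predict(object@fit, newdata = xgboost::xgb.DMatrix(Xs))
  }
})

#' @describeIn SurvModel-class one-line model summary
#' @param object a SurvModel.
#' @export
setMethod("show", "SurvModel", function(object) {
  cat(sprintf("SurvModel '%s' on %d features\n", object@name,
              length(object@center)))
})

#' Stratified cross-validated model evaluation
#'
#' Patient-level k-fold cross-validation, folds stratified by event
#' indicator, deterministic under `seed`. When `discretizeCols` names
#' columns of `X`, their maximally selected cutpoints are computed on each
#' training fold only and applied to both folds (no test-fold leakage); a
#' training-fold-constant column falls back to all zeros. Fold C-indices
#' use the Harrell tie-credit variant by default so that a degenerate
#' constant predictor scores chance level rather than zero.
#'
#' @param X feature matrix (patients x features).
#' @param records data.frame with `time`, `event` (and optionally
#'   `patient_id`) aligned with `X`.
#' @param models model names to evaluate.
#' @param k number of folds.
#' @param seed integer seed for fold assignment.
#' @param discretizeCols columns to maxstat-discretize per training fold.
#' @param minprop minimal group proportion for the cutpoint scan.
#' @param ties C-index tie handling for fold evaluation.
#' @param hyper named list of per-model hyperparameter lists.
#' @return data.frame with columns `model`, `mean_cindex`, `sd_cindex`;
#'   attributes `folds` (per-fold table) and `cutoffs` (per-fold cutpoint
#'   lists).
#' @export
crossValidate <- function(X, records, models = survModels(), k = 5L,
                          seed = 1L, discretizeCols = NULL, minprop = 0.1,
                          ties = c("harrell", "none"), hyper = list()) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  n <- nrow(X)
  records <- .checkRecords(records, n)
  if (n < k) stop("need at least k patients")
  fold <- integer(n)
  .withSeed(seed, {
    for (ev in unique(records$event)) {
      idx <- sample(which(records$event == ev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  foldRows <- list(); cutList <- list()
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (sum(records$event[tr]) == 0L)
      stop(sprintf("fold %d has no events in training data", f))
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (!is.null(discretizeCols)) {
      cuts <- list()
      for (cc in discretizeCols) {
        val <- tryCatch(
          maxstatCutoff(Xtr[, cc], records$time[tr], records$event[tr],
                        minprop = minprop, nperm = 0L)$cutoff,
          error = function(e) NA_real_)
        cuts[[cc]] <- val
        if (is.na(val)) {
          Xtr[, cc] <- 0; Xte[, cc] <- 0
        } else {
          Xtr[, cc] <- discretize(Xtr[, cc], val)
          Xte[, cc] <- discretize(Xte[, cc], val)
        }
      }
      cutList[[f]] <- cuts
    }
    recTr <- records[tr, , drop = FALSE]
    for (mm in models) {
      fit <- .withSeed(deriveSeed(seed, paste0("fit:", mm, ":", f)),
        fitSurvivalModel(mm, Xtr, recTr, hyper = hyper[[mm]] %||% list()))
      risk <- predictRisk(fit, Xte)
      ci <- concordanceIndex(records$time[te], records$event[te], risk,
                             ties = ties)
      foldRows[[length(foldRows) + 1L]] <-
        data.frame(model = mm, fold = f, cindex = ci, n_test = sum(te))
    }
  }
  folds <- do.call(rbind, foldRows)
  agg <- do.call(rbind, lapply(models, function(mm) {
    ci <- folds$cindex[folds$model == mm]
    data.frame(model = mm, mean_cindex = mean(ci), sd_cindex = sd(ci))
  }))
  attr(agg, "folds") <- folds
  attr(agg, "cutoffs") <- cutList
  attr(agg, "fold_assign") <- fold
  agg
}
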