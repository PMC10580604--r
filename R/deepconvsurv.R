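# Convolutional Cox partial-likelihood feature extraction. The network is a
# configurable conv stack (conv -> ReLU -> 2x2 mean pool per block) ending in
# a fully connected 32-unit hidden layer and a scalar risk head, trained with
# Adam on the negative log partial likelihood. Weights use He initialization.
# The contract is the 32-dimensional feature, not the backbone. Implemented
# directly on BLAS matrix products (im2col convolution with analytic
# backprop), which is adequate at the patch sizes this package targets.

#' Negative log Cox partial likelihood
#'
#' `-(1/D) * sum over events i of [ r_i - log sum_{j: T_j >= T_i} exp(r_j) ]`
#' with `D` the number of events. Tied event times are handled with the
#' Breslow convention: every subject with `T_j >= T_i` (ties included) is in
#' event `i`'s risk set.
#'
#' @param risks numeric risk scores, one per subject.
#' @param times positive observed times.
#' @param events 0/1 event indicators (1 = event observed).
#' @return non-negative scalar loss.
#' @examples
#' coxPartialNLL(0.3, 1, 1)                 # single subject: exactly 0
#' coxPartialNLL(c(1, 1), c(1, 2), c(1, 1)) # log(2) / 2
#' @export
coxPartialNLL <- function(risks, times, events) {
  n <- length(risks)
  stopifnot(length(times) == n, length(events) == n, all(times > 0),
            all(events %in% c(0, 1)), all(is.finite(risks)))
  E <- which(events == 1)
  if (length(E) == 0L) stop("at least one event is required")
  terms <- vapply(E, function(i) {
    risks[i] - .logsumexp(risks[times >= times[i]])
  }, numeric(1))
  -mean(terms)
}

#' Analytic gradient of the Cox partial likelihood loss
#'
#' Gradient of [coxPartialNLL()] with respect to the risk scores; matches
#' central finite differences to high precision (a property the test suite
#' checks on random instances).
#'
#' @inheritParams coxPartialNLL
#' @return numeric vector, same length as `risks`.
#' @export
coxPartialNLLGrad <- function(risks, times, events) {
  n <- length(risks)
  stopifnot(length(times) == n, length(events) == n)
  E <- which(events == 1)
  if (length(E) == 0L) stop("at least one event is required")
  g <- numeric(n)
  for (i in E) {
    rs <- which(times >= times[i])
    w <- exp(risks[rs] - .logsumexp(risks[rs]))
    g[rs] <- g[rs] + w
  }
  g[E] <- g[E] - 1
  g / length(E)
}

#' DeepConvSurv configuration
#'
#' @param edge input patch edge length in pixels (desk-scale default 32).
#' @param channels input channels (3 for RGB).
#' @param convFilters filter counts of the conv blocks; each block is
#'   conv(kernel) -> ReLU -> 2x2 mean pool.
#' @param kernel square conv kernel size.
#' @param fcWidth width of the feature layer (32 by default; the pipeline
#'   assumes 32 unless overridden consistently).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch batch size; batches are stratified so each contains at
#'   least one event (the partial likelihood is undefined otherwise).
#' @param seed integer seed for He initialization and batch shuffling.
#' @return list of class `deepConvSurvConfig`.
#' @export
deepConvSurvConfig <- function(edge = 32L, channels = 3L,
                               convFilters = c(8L, 16L, 32L), kernel = 3L,
                               fcWidth = 32L, lr = 1e-4, epochs = 10L,
                               batch = 32L, seed = 1L) {
  cfg <- list(edge = as.integer(edge), channels = as.integer(channels),
              convFilters = as.integer(convFilters), kernel = as.integer(kernel),
              fcWidth = as.integer(fcWidth), lr = lr,
              epochs = as.integer(epochs), batch = as.integer(batch),
              seed = as.integer(seed))
  # validate that the spatial size survives the stack
  h <- cfg$edge
  for (f in cfg$convFilters) {
    h <- h - cfg$kernel + 1L
    if (h < 2L) stop("conv stack shrinks the input below 2 pixels")
    h <- h %/% 2L
  }
  cfg$flatDim <- h * h * cfg$convFilters[length(cfg$convFilters)]
  structure(cfg, class = "deepConvSurvConfig")
}

# --- im2col convolution -----------------------------------------------------

.im2colIdx <- function(H, W, C, k) {
  Ho <- H - k + 1L; Wo <- W - k + 1L
  off <- as.vector(outer(outer(0:(k - 1L), (0:(k - 1L)) * H, "+"),
                         (seq_len(C) - 1L) * H * W, "+"))
  pos <- as.vector(outer(seq_len(Ho), (seq_len(Wo) - 1L) * H, "+"))
  list(idx = as.vector(outer(off, pos, "+")), Ho = Ho, Wo = Wo,
       kkC = k * k * C)
}

.convForward <- function(X, Wm, b, ic) {
  d <- dim(X)  # H, W, C, N
  N <- d[4]
  Xf <- matrix(X, d[1] * d[2] * d[3], N)
  Am <- matrix(Xf[ic$idx, , drop = FALSE], nrow = ic$kkC)
  Z <- crossprod(Wm, Am) + b               # F x (P0*N)
  out <- aperm(array(Z, c(ncol(Wm), ic$Ho, ic$Wo, N)), c(2, 3, 1, 4))
  list(out = out, Am = Am, dims = d)
}

.convBackward <- function(dOut, Wm, cache, ic) {
  d <- cache$dims; N <- d[4]
  dZ <- matrix(aperm(dOut, c(3, 1, 2, 4)), nrow = ncol(Wm))
  db <- rowSums(dZ)
  dW <- tcrossprod(cache$Am, dZ)
  dAm <- Wm %*% dZ
  dPm <- matrix(dAm, nrow = ic$kkC * ic$Ho * ic$Wo)
  dXf <- matrix(0, d[1] * d[2] * d[3], N)
  rs <- rowsum(dPm, ic$idx)
  dXf[as.integer(rownames(rs)), ] <- rs
  list(dX = array(dXf, d), dW = dW, db = db)
}

.poolForward <- function(X) {
  d <- dim(X)
  Hc <- (d[1] %/% 2L) * 2L; Wc <- (d[2] %/% 2L) * 2L
  i1 <- seq(1L, Hc, 2L); j1 <- seq(1L, Wc, 2L)
  (X[i1, j1, , , drop = FALSE] + X[i1 + 1L, j1, , , drop = FALSE] +
   X[i1, j1 + 1L, , , drop = FALSE] + X[i1 + 1L, j1 + 1L, , , drop = FALSE]) / 4
}

.poolBackward <- function(dOut, inDims) {
  dX <- array(0, inDims)
  d <- dim(dOut)
  i1 <- seq(1L, d[1] * 2L, 2L); j1 <- seq(1L, d[2] * 2L, 2L)
  g <- dOut / 4
  dX[i1, j1, , ] <- g
  dX[i1 + 1L, j1, , ] <- g
  dX[i1, j1 + 1L, , ] <- g
  dX[i1 + 1L, j1 + 1L, , ] <- g
  dX
}

# --- network ----------------------------------------------------------------

.heInit <- function(nrow, ncol, fanIn) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fanIn)), nrow, ncol)
}

.initNet <- function(cfg) {
  params <- list(conv = list())
  Cin <- cfg$channels
  for (l in seq_along(cfg$convFilters)) {
    f <- cfg$convFilters[l]
    fan <- cfg$kernel^2 * Cin
    params$conv[[l]] <- list(W = .heInit(fan, f, fan), b = numeric(f))
    Cin <- f
  }
  params$fc1 <- list(W = .heInit(cfg$flatDim, cfg$fcWidth, cfg$flatDim),
                     b = numeric(cfg$fcWidth))
  params$fc2 <- list(W = .heInit(cfg$fcWidth, 1L, cfg$fcWidth),
                     b = numeric(1L))
  params
}

.netICs <- function(cfg) {
  ics <- list()
  H <- cfg$edge; Cin <- cfg$channels
  for (l in seq_along(cfg$convFilters)) {
    ics[[l]] <- .im2colIdx(H, H, Cin, cfg$kernel)
    H <- (H - cfg$kernel + 1L) %/% 2L
    Cin <- cfg$convFilters[l]
  }
  ics
}

# forward pass; returns risks (length N), fc1 post-ReLU features (width x N),
# and caches for backprop
.netForward <- function(X, params, cfg, ics) {
  caches <- list(conv = list())
  A <- X
  for (l in seq_along(params$conv)) {
    cf <- .convForward(A, params$conv[[l]]$W, params$conv[[l]]$b, ics[[l]])
    relu <- pmax(cf$out, 0)
    caches$conv[[l]] <- list(cache = cf, mask = cf$out > 0,
                             poolIn = dim(relu))
    A <- .poolForward(relu)
  }
  flat <- matrix(A, cfg$flatDim, dim(X)[4])
  z1 <- crossprod(params$fc1$W, flat) + params$fc1$b
  h1 <- pmax(z1, 0)
  risk <- drop(crossprod(params$fc2$W, h1) + params$fc2$b)
  caches$flat <- flat; caches$z1 <- z1; caches$h1 <- h1
  caches$lastDims <- dim(A)
  list(risk = risk, features = h1, caches = caches)
}

.netBackward <- function(dRisk, params, cfg, ics, caches) {
  N <- length(dRisk)
  grads <- list(conv = vector("list", length(params$conv)))
  dRisk <- matrix(dRisk, 1L, N)
  grads$fc2 <- list(W = tcrossprod(caches$h1, dRisk),
                    b = sum(dRisk))
  dh1 <- params$fc2$W %*% dRisk
  dz1 <- dh1 * (caches$z1 > 0)
  grads$fc1 <- list(W = tcrossprod(caches$flat, dz1),
                    b = rowSums(dz1))
  dflat <- params$fc1$W %*% dz1
  dA <- array(dflat, caches$lastDims)
  for (l in rev(seq_along(params$conv))) {
    cc <- caches$conv[[l]]
    dRelu <- .poolBackward(dA, cc$poolIn)
    dPre <- dRelu * cc$mask
    cb <- .convBackward(dPre, params$conv[[l]]$W, cc$cache, ics[[l]])
    grads$conv[[l]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  # keep the element order identical to the params list (Adam walks the two
  # structures positionally)
  grads[c("conv", "fc1", "fc2")]
}

# --- Adam -------------------------------------------------------------------

.adamInit <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

.adamStep <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk(params, grads, state$m, state$v)
}

.patchBatch <- function(patches, idx, cfg) {
  array(unlist(patches[idx], use.names = FALSE),
        c(cfg$edge, cfg$edge, cfg$channels, length(idx)))
}

#' Train a per-tissue DeepConvSurv feature extractor
#'
#' Trains the conv network on patches of one tissue type, each patch
#' carrying its patient's overall-survival label `(time, event)`. He
#' initialization, Adam, negative log Cox partial likelihood on the scalar
#' risk head. Batches are built so every batch holds at least one event.
#' Deterministic under the config seed.
#'
#' @param patches list of `edge x edge x channels` arrays.
#' @param times,events per-patch inherited patient survival labels.
#' @param cfg a [deepConvSurvConfig()].
#' @param patient_id optional per-patch patient ids (at least two distinct
#'   patients are required when given).
#' @return a [DeepConvSurv-class] extractor.
#' @export
trainTissueExtractor <- function(patches, times, events,
                                 cfg = deepConvSurvConfig(),
                                 patient_id = NULL) {
  n <- length(patches)
  stopifnot(n == length(times), n == length(events))
  if (!is.null(patient_id) && length(unique(patient_id)) < 2L)
    stop("at least two distinct patients are required")
  if (sum(events) == 0L) stop("all-censored input: partial likelihood undefined")
  ics <- .netICs(cfg)
  .withSeed(cfg$seed, {
    params <- .initNet(cfg)
    state <- list(m = .adamInit(params), v = .adamInit(params))
    t <- 0L
    trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      evIdx <- sample(which(events == 1))
      cenIdx <- sample(which(events == 0))
      nb <- max(1L, min(ceiling(n / cfg$batch), length(evIdx)))
      assign <- integer(n)
      assign[evIdx] <- rep_len(seq_len(nb), length(evIdx))
      if (length(cenIdx))
        assign[cenIdx] <- rep_len(seq_len(nb), length(cenIdx))
      losses <- numeric(nb)
      for (bidx in seq_len(nb)) {
        sel <- which(assign == bidx)
        X <- .patchBatch(patches, sel, cfg)
        fw <- .netForward(X, params, cfg, ics)
        losses[bidx] <- coxPartialNLL(fw$risk, times[sel], events[sel])
        dRisk <- coxPartialNLLGrad(fw$risk, times[sel], events[sel])
        grads <- .netBackward(dRisk, params, cfg, ics, fw$caches)
        t <- t + 1L
        upd <- .adamStep(params, grads, state, cfg$lr, t)
        params <- upd$p
        state <- list(m = upd$m, v = upd$v)
      }
      trace[ep] <- mean(losses)
    }
    new("DeepConvSurv", params = params, config = unclass(cfg),
        tissue = NA_character_, trace = trace)
  })
}

#' @rdname patchFeatures
#' @export
setMethod("patchFeatures", "DeepConvSurv", function(object, patches, ...) {
  cfg <- structure(object@config, class = "deepConvSurvConfig")
  ics <- .netICs(cfg)
  chunks <- split(seq_along(patches),
                  ceiling(seq_along(patches) / 256))
  out <- lapply(chunks, function(sel) {
    X <- .patchBatch(patches, sel, cfg)
    t(.netForward(X, object@params, cfg, ics)$features)
  })
  feats <- do.call(rbind, out)
  rownames(feats) <- NULL
  feats
})

#' @rdname predictRisk
#' @export
setMethod("predictRisk", "DeepConvSurv", function(object, newdata, ...) {
  cfg <- structure(object@config, class = "deepConvSurvConfig")
  ics <- .netICs(cfg)
  chunks <- split(seq_along(newdata), ceiling(seq_along(newdata) / 256))
  unlist(lapply(chunks, function(sel) {
    X <- .patchBatch(newdata, sel, cfg)
    .netForward(X, object@params, cfg, ics)$risk
  }), use.names = FALSE)
})

#' @describeIn DeepConvSurv-class training summary
#' @param object a DeepConvSurv.
#' @export
setMethod("show", "DeepConvSurv", function(object) {
  cfg <- object@config
  cat(sprintf(
    "DeepConvSurv (%s): %d-px input, conv %s, FC-%d features, %d epochs\n",
    ifelse(is.na(object@tissue), "untagged", object@tissue), cfg$edge,
    paste(cfg$convFilters, collapse = "-"), cfg$fcWidth,
    length(object@trace)))
  if (length(object@trace))
    cat(sprintf("  loss %.4f -> %.4f\n", object@trace[1],
                object@trace[length(object@trace)]))
})

# --- aggregation ------------------------------------------------------------

#' Weighted per-tissue aggregation of patch features
#'
#' The tissue-level feature is the mean of its patch features multiplied by
#' the tissue's patch share: `(n_t / n_total) * colMeans(features)`, where
#' `n_total` counts all sampled non-background patches of the slide. A
#' tissue with no patches contributes a zero vector.
#'
#' @param features `n_t x width` matrix of patch features (or NULL when
#'   `n_t = 0`).
#' @param n_t patch count of this tissue.
#' @param n_total all sampled non-BACK patches (> 0).
#' @param width feature width used for the zero vector when `n_t = 0`.
#' @return numeric vector of length `width`.
#' @examples
#' aggregateTissue(matrix(1, 10, 32), 10, 40)[1]  # 0.25
#' @export
aggregateTissue <- function(features, n_t, n_total, width = 32L) {
  if (n_total <= 0L) stop("n_total must be positive")
  if (n_t > n_total) stop("n_t cannot exceed n_total")
  if (n_t == 0L) return(numeric(width))
  stopifnot(is.matrix(features), nrow(features) == n_t)
  (n_t / n_total) * colMeans(features)
}

#' Concatenate per-tissue vectors into the histopathological feature
#'
#' Fixed tissue order (default TUM, LYM, STR, MUC); the result has width
#' `32 * |tissues|` (128 for the default four-tissue set). Zero vectors are
#' allowed; mismatched widths are an error.
#'
#' @param vectors named list of per-tissue feature vectors.
#' @param tissues tissue order; must all be present in `vectors`.
#' @return named numeric vector (names `TISSUE_k`).
#' @export
concatHisto <- function(vectors, tissues = c("TUM", "LYM", "STR", "MUC")) {
  if (!all(tissues %in% names(vectors)))
    stop("missing tissue vectors: ",
         paste(setdiff(tissues, names(vectors)), collapse = ", "))
  w <- unique(vapply(vectors[tissues], length, integer(1)))
  if (length(w) != 1L) stop("per-tissue feature widths differ")
  out <- unlist(lapply(tissues, function(tt) {
    v <- vectors[[tt]]
    names(v) <- sprintf("%s_%d", tt, seq_along(v))
    v
  }))
  out
}

#' Enumerate non-empty tissue subsets
#'
#' @param tissues character vector of tissue classes (no BACK).
#' @return list of character vectors, all `2^m - 1` non-empty subsets,
#'   ordered by size then lexicographically within size.
#' @examples
#' length(tissueCombinations(setdiff(tissueClasses(), "BACK")))  # 255
#' @export
tissueCombinations <- function(tissues) {
  stopifnot(length(tissues) >= 1L, !"BACK" %in% tissues)
  out <- list()
  for (sz in seq_along(tissues)) {
    cmb <- combn(tissues, sz, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Search tissue combinations by cross-validated concordance
#'
#' Evaluates every non-empty subset of the supplied tissue feature blocks
#' (all `2^m - 1` of them; 255 for the eight non-background classes) by the
#' cross-validated C-index of each survival model on the concatenated
#' feature matrix, and returns a ranked table.
#'
#' @param featuresByTissue named list of `n x width` per-patient feature
#'   matrices, one per tissue.
#' @param records data.frame with columns time, event (and optionally
#'   patient_id), aligned with the feature rows.
#' @param models survival model names (see [survModels()]).
#' @param k cross-validation folds.
#' @param seed integer seed.
#' @param evalFun optional replacement evaluator
#'   `function(X, records) -> named numeric` (mean C-index per model);
#'   useful for cheap screening.
#' @return data.frame with columns subset, size, model, mean_cindex,
#'   sorted by decreasing mean_cindex.
#' @export
tissueCombinationSearch <- function(featuresByTissue, records,
                                    models = "ridge_cox", k = 5L, seed = 1L,
                                    evalFun = NULL) {
  subsets <- tissueCombinations(names(featuresByTissue))
  if (is.null(evalFun)) {
    evalFun <- function(X, records) {
      cv <- crossValidate(X, records, models = models, k = k, seed = seed)
      stats::setNames(cv$mean_cindex, cv$model)
    }
  }
  rows <- lapply(subsets, function(ss) {
    X <- do.call(cbind, featuresByTissue[ss])
    sc <- evalFun(X, records)
    data.frame(subset = paste(ss, collapse = "+"), size = length(ss),
               model = names(sc) %||% models, mean_cindex = as.numeric(sc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_cindex), , drop = FALSE]
}
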