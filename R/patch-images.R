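# Class-distinguishable synthetic patch textures and the nine-class patch
# classifier. The texture family is: class mean color + optional oriented
# sinusoidal stripes (class-specific spatial frequency) + Gaussian pixel
# noise, so classifier learnability is controlled by one noise parameter.

# per-class texture parameters: mean RGB, stripe frequency (cycles per
# patch; 0 = none), stripe orientation (1 = rows, 2 = cols)
.textureParams <- function() {
  list(
    ADI  = list(mean = c(0.92, 0.88, 0.90), freq = 0, orient = 1),
    BACK = list(mean = c(0.97, 0.97, 0.97), freq = 0, orient = 1),
    DEB  = list(mean = c(0.55, 0.45, 0.35), freq = 2, orient = 2),
    LYM  = list(mean = c(0.35, 0.30, 0.62), freq = 0, orient = 1),
    MUC  = list(mean = c(0.75, 0.75, 0.88), freq = 1, orient = 2),
    MUS  = list(mean = c(0.80, 0.60, 0.55), freq = 6, orient = 1),
    NORM = list(mean = c(0.72, 0.52, 0.45), freq = 3, orient = 1),
    STR  = list(mean = c(0.72, 0.55, 0.65), freq = 4, orient = 2),
    TUM  = list(mean = c(0.62, 0.32, 0.52), freq = 5, orient = 1))
}

#' Generate synthetic patch images for one tissue class
#'
#' Draws `n` RGB patches from the class's texture family (distinct mean
#' color and stripe frequency per class, plus Gaussian noise). Deterministic
#' under `seed`. `intensity` adds a uniform brightness shift, used by the
#' cohort pipeline to let patch appearance carry survival signal.
#'
#' @param tissue_class one of [tissueClasses()].
#' @param n number of patches (>= 1).
#' @param edge patch edge length in pixels (>= 8).
#' @param seed integer seed (NULL = use current RNG state).
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param intensity additive brightness shift before clipping.
#' @return list of `edge x edge x 3` arrays with values in `[0, 1]`.
#' @examples
#' p <- generatePatchImages("TUM", n = 2, edge = 16, seed = 1)
#' dim(p[[1]])
#' @export
generatePatchImages <- function(tissue_class, n, edge = 32L, seed = NULL,
                                noise_sd = 0.08, intensity = 0) {
  params <- .textureParams()
  if (!tissue_class %in% names(params))
    stop(sprintf("unknown tissue class '%s'", tissue_class))
  if (n < 1L) stop("n must be >= 1")
  if (edge < 8L) stop("edge must be >= 8")
  p <- params[[tissue_class]]
  .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      base <- array(rep(p$mean, each = edge * edge), c(edge, edge, 3))
      if (p$freq > 0) {
        phase <- runif(1, 0, 2 * pi)
        wave <- 0.08 * sin(2 * pi * p$freq * seq_len(edge) / edge + phase)
        stripe <- if (p$orient == 1) matrix(wave, edge, edge)
                  else matrix(wave, edge, edge, byrow = TRUE)
        base <- base + array(rep(stripe, 3), c(edge, edge, 3))
      }
      img <- base + intensity +
        array(rnorm(edge * edge * 3, sd = noise_sd), c(edge, edge, 3))
      pmin(pmax(img, 0), 1)
    })
  })
}

# mean-pool a patch to a pool x pool x 3 feature vector
.poolPatch <- function(img, pool = 4L) {
  edge <- dim(img)[1]
  cuts <- cut(seq_len(edge), pool, labels = FALSE)
  out <- numeric(pool * pool * 3)
  k <- 0L
  for (ch in 1:3) for (j in seq_len(pool)) for (i in seq_len(pool)) {
    k <- k + 1L
    out[k] <- mean(img[cuts == i, cuts == j, ch])
  }
  out
}

#' Train the nine-class patch classifier
#'
#' Fits a single-hidden-layer softmax network (cross-entropy loss, via
#' \pkg{nnet}) on mean-pooled pixel features. Deterministic under `seed`.
#'
#' @param patches list of patch arrays.
#' @param labels character vector of tissue-class labels, one per patch.
#' @param hidden hidden layer width.
#' @param pool pooling factor for pixel features (`pool^2 * 3` inputs).
#' @param maxit maximum optimizer iterations.
#' @param decay weight decay.
#' @param seed integer seed.
#' @return a [PatchClassifier-class].
#' @export
trainPatchClassifier <- function(patches, labels, hidden = 16L, pool = 4L,
                                 maxit = 150L, decay = 1e-4, seed = 1L) {
  if (length(patches) == 0L) stop("empty training set")
  if (length(patches) != length(labels))
    stop("patches and labels must align")
  if (!all(labels %in% tissueClasses()))
    stop("labels must be valid tissue classes")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("at least two classes required")
  X <- t(vapply(patches, .poolPatch, numeric(pool * pool * 3), pool = pool))
  Y <- nnet::class.ind(factor(labels, levels = classes))
  fit <- .withSeed(seed,
    nnet::nnet(X, Y, size = hidden, softmax = TRUE, maxit = maxit,
               decay = decay, trace = FALSE, MaxNWts = 100000))
  new("PatchClassifier", fit = fit, classes = classes, type = "nnet",
      pool = as.integer(pool))
}

#' Oracle classifier from generator ground truth
#'
#' Returns planted labels with confidence 1; used to isolate downstream
#' stages from classifier error. Classifies by grid position rather than by
#' pixel content.
#'
#' @param maps a [TissueMap-class] or a named list of them (one per slide).
#' @return a [PatchClassifier-class] of type `"oracle"`.
#' @export
oracleClassifier <- function(maps) {
  if (is(maps, "TissueMap")) maps <- stats::setNames(list(maps), slideID(maps))
  stopifnot(all(vapply(maps, is, logical(1), "TissueMap")))
  new("PatchClassifier", fit = maps,
      classes = tissueClasses(), type = "oracle", pool = 1L)
}

#' @rdname classifyPatches
#' @export
setMethod("classifyPatches", "PatchClassifier", function(object, patches, ...) {
  if (object@type == "oracle") {
    stopifnot(is.data.frame(patches), all(c("row", "col") %in% names(patches)))
    maps <- object@fit
    sid <- if ("slide_id" %in% names(patches)) patches$slide_id
           else rep(names(maps)[1], nrow(patches))
    cls <- vapply(seq_len(nrow(patches)), function(k) {
      as.matrix(maps[[sid[k]]])[patches$row[k], patches$col[k]]
    }, character(1))
    return(data.frame(class = cls, confidence = 1, stringsAsFactors = FALSE))
  }
  X <- t(vapply(patches, .poolPatch,
                numeric(object@pool * object@pool * 3), pool = object@pool))
  pr <- predict(object@fit, X)
  idx <- max.col(pr, ties.method = "first")
  data.frame(class = object@classes[idx],
             confidence = pr[cbind(seq_len(nrow(pr)), idx)],
             stringsAsFactors = FALSE)
})
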