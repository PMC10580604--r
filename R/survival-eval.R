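# Concordance index, Kaplan-Meier, log-rank, maximally selected rank
# statistic cutpoints, feature merging, the six survival models, and
# cross-validated evaluation.

#' Concordance index
#'
#' Literal pairwise definition: over pairs with `i` uncensored and
#' `T_j > T_i`, the fraction in which `R_i > R_j` (strict inequalities).
#' A value of 1 is perfect ranking, 0.5 a random guess. `ties = "harrell"`
#' gives tied risks 0.5 credit (Harrell's variant); the default gives no
#' tie credit.
#'
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @param risks predicted risks (higher = worse).
#' @param ties `"none"` (strict, the default) or `"harrell"`.
#' @return C-index in `[0, 1]`.
#' @examples
#' concordanceIndex(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1))  # 1
#' concordanceIndex(c(1, 2, 3, 4), c(1, 1, 1, 1), c(4, 3, 1, 2))  # 5/6
#' @export
concordanceIndex <- function(times, events, risks,
                             ties = c("none", "harrell")) {
  ties <- match.arg(ties)
  n <- length(times)
  stopifnot(length(events) == n, length(risks) == n, all(is.finite(risks)))
  cmp <- outer(times, times, "<")          # cmp[i, j] : T_j > T_i
  cmp[events == 0, ] <- FALSE              # i must be uncensored
  den <- sum(cmp)
  if (den == 0) stop("no comparable pairs")
  conc <- outer(risks, risks, ">")
  num <- sum(cmp & conc)
  if (ties == "harrell") num <- num + 0.5 * sum(cmp & outer(risks, risks, "=="))
  num / den
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous step function starting at 1, dropping at each event
#' time by the factor `1 - d/n` (events over at-risk).
#'
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @return data.frame of class `kmFit` with columns `time`, `n.risk`,
#'   `n.event`, `n.censor`, `surv` (one row per distinct observed time).
#' @export
kaplanMeier <- function(times, events) {
  n <- length(times)
  stopifnot(n >= 1L, length(events) == n)
  ut <- sort(unique(times))
  nRisk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  nEvent <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  nCens <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  structure(data.frame(time = ut, n.risk = nRisk, n.event = nEvent,
                       n.censor = nCens, surv = surv),
            class = c("kmFit", "data.frame"))
}

#' Evaluate a Kaplan-Meier fit at arbitrary times
#'
#' @param km a [kaplanMeier()] fit.
#' @param t numeric times.
#' @return survival probabilities (1 before the first observed time).
#' @export
kmSurvival <- function(km, t) {
  vapply(t, function(tt) {
    idx <- which(km$time <= tt)
    if (length(idx) == 0L) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank statistic with one degree of freedom:
#' at each distinct event time, observed minus hypergeometric-expected
#' events in group 1, variance-summed.
#'
#' @param times,events survival data.
#' @param group two-level group labels.
#' @return list with `statistic`, `p.value`, `observed`, `expected`
#'   (group-1 totals).
#' @export
logrankTest <- function(times, events, group) {
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2L) stop("exactly two non-empty groups required")
  stopifnot(length(times) == length(g), length(events) == length(g))
  ut <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    atRisk <- times >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g == 1L)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

# log-rank (Nelson-Aalen) scores: a_i = event_i - cumhaz(T_i)
.logrankScores <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  haz <- vapply(ut, function(t) {
    sum(times == t & events == 1) / sum(times >= t)
  }, numeric(1))
  cumhaz <- cumsum(haz)
  H <- vapply(times, function(tt) {
    idx <- which(ut <= tt)
    if (length(idx) == 0L) 0 else cumhaz[max(idx)]
  }, numeric(1))
  events - H
}

# standardized statistic for splitting scores `a` at "x > cutoff" groups of
# size m, under the permutation (conditional) null
.maxstatZ <- function(S, m, n, aBar, aVar) {
  V <- m * (n - m) / (n - 1) * aVar
  ifelse(V > 0, (S - m * aBar) / sqrt(V), 0)
}

#' Maximally selected rank statistic cutpoint
#'
#' Scans all admissible cutpoints (both groups at least `minprop` of the
#' cohort) of the form `x > cutoff` and selects the one maximizing the
#' absolute standardized log-rank statistic, computed from Nelson-Aalen
#' log-rank scores with the conditional permutation mean and variance. The
#' p-value is obtained by permuting the feature values against the
#' outcomes and re-maximizing, which is honest about the multiplicity of
#' the scan.
#'
#' @param x numeric feature values (at least two distinct).
#' @param times,events survival data (at least one event).
#' @param minprop minimal group proportion for admissible cutoffs.
#' @param nperm permutations for the p-value (0 = skip, p is NA).
#' @param seed integer seed for the permutations.
#' @return list of class `cutoffResult` with `cutoff`, `statistic`
#'   (max |z|), `p.value`, `n.high`, `n.low`, and the scanned `candidates`
#'   table.
#' @export
maxstatCutoff <- function(x, times, events, minprop = 0.1, nperm = 1000L,
                          seed = NULL) {
  n <- length(x)
  stopifnot(length(times) == n, length(events) == n)
  if (length(unique(x)) < 2L) stop("constant feature: no cutpoint exists")
  if (sum(events) == 0L) stop("at least one event is required")
  a <- .logrankScores(times, events)
  aBar <- mean(a)
  aVar <- sum((a - aBar)^2) / n
  ord <- order(x)
  xs <- x[ord]; as_ <- a[ord]
  # S_k = sum of scores with x > xs[k]; candidate cutoffs at boundaries
  # between distinct consecutive values
  suffix <- rev(cumsum(rev(as_)))          # suffix[k] = sum(as_[k:n])
  kCand <- which(xs[-n] < xs[-1])          # split after position k
  m <- n - kCand
  lo <- ceiling(minprop * n); hi <- floor((1 - minprop) * n)
  ok <- m >= max(1L, lo) & m <= min(n - 1L, hi)
  kCand <- kCand[ok]; m <- m[ok]
  if (length(kCand) == 0L) stop("no admissible cutpoint under minprop")
  S <- suffix[kCand + 1L]
  z <- .maxstatZ(S, m, n, aBar, aVar)
  best <- which.max(abs(z))
  obs <- abs(z[best])
  pval <- NA_real_
  if (nperm > 0L) {
    exceed <- .withSeed(seed, {
      sum(vapply(seq_len(nperm), function(b) {
        ap <- sample(a)
        sfx <- rev(cumsum(rev(ap[ord])))   # ord irrelevant after permuting,
        Sp <- sfx[kCand + 1L]              # kept for symmetry with observed
        max(abs(.maxstatZ(Sp, m, n, aBar, aVar))) >= obs
      }, logical(1)))
    })
    pval <- (1 + exceed) / (1 + nperm)
  }
  structure(list(cutoff = xs[kCand[best]], statistic = obs, p.value = pval,
                 n.high = m[best], n.low = n - m[best],
                 candidates = data.frame(cutoff = xs[kCand], m = m, z = z)),
            class = "cutoffResult")
}

#' @export
print.cutoffResult <- function(x, ...) {
  cat(sprintf("maxstat cutpoint %.6g (|z| = %.3f, p = %s; high %d / low %d)\n",
              x$cutoff, x$statistic,
              ifelse(is.na(x$p.value), "NA", format(x$p.value)),
              x$n.high, x$n.low))
  invisible(x)
}

#' Discretize a feature at a cutpoint
#'
#' Strict rule: 1 iff `value > cutoff`, else 0 (a value equal to the
#' cutoff maps to 0).
#'
#' @param x numeric values.
#' @param cutoff scalar cutpoint.
#' @return integer 0/1 vector.
#' @export
discretize <- function(x, cutoff) {
  stopifnot(all(is.finite(x)), is.finite(cutoff))
  as.integer(x > cutoff)
}

#' Merge histopathological and discretized area features
#'
#' Concatenation with the histopathological block first and the five
#' discretized area features (in [areaFeatureNames()] order) second:
#' 128 + 5 = 133 columns for the default four-tissue set.
#'
#' @param histo numeric matrix (or vector) of histopathological features,
#'   width 128 by default.
#' @param areaBinary matrix (or vector) of the 5 discretized area features.
#' @param histoWidth,areaWidth expected widths (checked).
#' @return numeric matrix of width `histoWidth + areaWidth`.
#' @export
mergeFeatures <- function(histo, areaBinary, histoWidth = 128L,
                          areaWidth = 5L) {
  if (is.vector(histo)) histo <- matrix(histo, nrow = 1,
                                        dimnames = list(NULL, names(histo)))
  if (is.vector(areaBinary)) areaBinary <- matrix(areaBinary, nrow = 1)
  if (ncol(histo) != histoWidth)
    stop(sprintf("histopathological block must have %d columns, got %d",
                 histoWidth, ncol(histo)))
  if (ncol(areaBinary) != areaWidth)
    stop(sprintf("area block must have %d columns, got %d",
                 areaWidth, ncol(areaBinary)))
  if (is.null(colnames(areaBinary)))
    colnames(areaBinary) <- head(areaFeatureNames(), areaWidth)
  cbind(histo, areaBinary)
}
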