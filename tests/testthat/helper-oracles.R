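# Independent brute-force oracles. These deliberately share no code with the
# package implementations: neighborhood scans instead of shift unions,
# label-propagation relaxation instead of flood fill, double loops instead
# of vectorized outer products.

oracleDilate <- function(mask, h = 3L, w = 3L) {
  nr <- nrow(mask); nc <- ncol(mask)
  hh <- h %/% 2L; hw <- w %/% 2L
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (di in -hh:hh) for (dj in -hw:hw) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj] == 1)
        hit <- TRUE
    }
    out[i, j] <- as.integer(hit)
  }
  out
}

oracleErode <- function(mask, h = 3L, w = 3L) {
  nr <- nrow(mask); nc <- ncol(mask)
  hh <- h %/% 2L; hw <- w %/% 2L
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    all1 <- TRUE
    for (di in -hh:hh) for (dj in -hw:hw) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || mask[ii, jj] == 0)
        all1 <- FALSE
    }
    out[i, j] <- as.integer(all1)
  }
  out
}

oracleClosing <- function(mask, h = 3L, w = 3L) {
  # dilate on a zero-padded domain, erode, crop back
  hh <- h %/% 2L; hw <- w %/% 2L
  pad <- matrix(0L, nrow(mask) + 2L * hh, ncol(mask) + 2L * hw)
  pad[hh + seq_len(nrow(mask)), hw + seq_len(ncol(mask))] <- mask
  cl <- oracleErode(oracleDilate(pad, h, w), h, w)
  cl[hh + seq_len(nrow(mask)), hw + seq_len(ncol(mask)), drop = FALSE]
}

# component count and areas by min-label propagation until fixpoint
oracleComponents <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[mask == 0] <- 0L
  offs <- if (connectivity == 4L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else {
            o <- list()
            for (di in -1:1) for (dj in -1:1)
              if (di != 0 || dj != 0) o[[length(o) + 1L]] <- c(di, dj)
            o
          }
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (mask[i, j] == 1) {
        for (o in offs) {
          ii <- i + o[1]; jj <- j + o[2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] == 1 && lab[ii, jj] < lab[i, j]) {
            lab[i, j] <- lab[ii, jj]
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  roots <- sort(unique(lab[lab > 0]))
  list(n = length(roots),
       areas = sort(as.integer(table(lab[lab > 0]))))
}

# border-flood hole filling on the complement (4-connectivity)
oracleFillHoles <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  comp <- oracleComponentsLabels(1L - pad, 4L)
  borderLabels <- unique(c(comp[1, ], comp[nr + 2, ], comp[, 1],
                           comp[, nc + 2]))
  borderLabels <- borderLabels[borderLabels > 0]
  inner <- comp[2:(nr + 1), 2:(nc + 1)]
  out <- mask
  out[mask == 0 & !(inner %in% borderLabels)] <- 1L
  out
}

oracleComponentsLabels <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[mask == 0] <- 0L
  offs <- if (connectivity == 4L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else {
            o <- list()
            for (di in -1:1) for (dj in -1:1)
              if (di != 0 || dj != 0) o[[length(o) + 1L]] <- c(di, dj)
            o
          }
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (mask[i, j] == 1) {
        for (o in offs) {
          ii <- i + o[1]; jj <- j + o[2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] == 1 && lab[ii, jj] < lab[i, j]) {
            lab[i, j] <- lab[ii, jj]
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  lab
}

# literal double-loop concordance index
oracleCIndex <- function(times, events, risks, harrell = FALSE) {
  num <- 0; den <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (times[j] > times[i]) {
        den <- den + 1
        if (risks[i] > risks[j]) num <- num + 1
        else if (harrell && risks[i] == risks[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# naive per-cutoff maximally selected statistic scan (scores recomputed
# from scratch; direct group sums, no suffix-sum tricks)
oracleMaxstat <- function(x, times, events, minprop = 0.1) {
  n <- length(x)
  # Nelson-Aalen scores
  ut <- sort(unique(times[events == 1]))
  H <- numeric(n)
  for (i in seq_len(n)) {
    h <- 0
    for (t in ut) {
      if (t <= times[i])
        h <- h + sum(times == t & events == 1) / sum(times >= t)
    }
    H[i] <- h
  }
  a <- events - H
  aBar <- mean(a)
  ss <- sum((a - aBar)^2)
  cand <- sort(unique(x))
  cand <- cand[-length(cand)]
  best <- NULL
  for (mu in cand) {
    g <- x > mu
    m <- sum(g)
    if (m < max(1, ceiling(minprop * n)) ||
        m > min(n - 1, floor((1 - minprop) * n))) next
    S <- sum(a[g])
    V <- m * (n - m) / (n * (n - 1)) * ss
    z <- if (V > 0) abs(S - m * aBar) / sqrt(V) else 0
    if (is.null(best) || z > best$z) best <- list(cutoff = mu, z = z)
  }
  best
}

randomMask <- function(nr, nc, p = 0.4) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}

maskFromBits <- function(bits, nr = 4L, nc = 4L) {
  matrix(as.integer(intToBits(bits)[1:(nr * nc)] == 1), nr, nc)
}
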