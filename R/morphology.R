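# Binary grid morphology: dilation, erosion, closing, connected components,
# hole filling. Cells outside the grid are treated as background (zero
# padding), which keeps closing extensive on the observed domain.

#' Morphology configuration
#'
#' Rectangular structuring element (SE) with odd dimensions, centered on the
#' cell, and the connectivity used for component labeling. The defaults are
#' the ones used by the tissue-area stage: a 5 x 5 rectangle and
#' 8-connectivity.
#'
#' @param height,width odd SE dimensions in cells.
#' @param connectivity 4 or 8.
#' @return a list of class `morphConfig`.
#' @examples
#' morphConfig()           # 5x5 SE, 8-connected
#' morphConfig(3, 3, 4)
#' @export
morphConfig <- function(height = 5L, width = 5L, connectivity = 8L) {
  height <- as.integer(height); width <- as.integer(width)
  connectivity <- as.integer(connectivity)
  if (height < 1L || width < 1L || height %% 2L == 0L || width %% 2L == 0L)
    stop("structuring element dimensions must be odd positive integers")
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8")
  structure(list(height = height, width = width, connectivity = connectivity),
            class = "morphConfig")
}

.checkMask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- mask
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  m
}

# shift matrix by (di, dj), zero-filling vacated cells
.shiftMask <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rlo <- max(1L, 1L + di); rhi <- min(nr, nr + di)
  clo <- max(1L, 1L + dj); chi <- min(nc, nc + dj)
  if (rlo > rhi || clo > chi) return(out)
  out[rlo:rhi, clo:chi] <- m[(rlo - di):(rhi - di), (clo - dj):(chi - dj)]
  out
}

#' Binary dilation
#'
#' A cell of the output is foreground iff any cell under the centered
#' structuring element is foreground; out-of-grid cells count as background.
#'
#' @param mask 0/1 matrix.
#' @param cfg a [morphConfig()].
#' @return 0/1 integer matrix of the same shape.
#' @export
binaryDilate <- function(mask, cfg = morphConfig()) {
  m <- .checkMask(mask)
  hh <- cfg$height %/% 2L; hw <- cfg$width %/% 2L
  out <- matrix(0L, nrow(m), ncol(m))
  for (di in -hh:hh) for (dj in -hw:hw) {
    out <- pmax(out, .shiftMask(m, di, dj))
  }
  out
}

#' Binary erosion
#'
#' A cell of the output is foreground iff every cell under the centered
#' structuring element is foreground; out-of-grid cells count as background,
#' so foreground touching the border erodes inward.
#'
#' @inheritParams binaryDilate
#' @return 0/1 integer matrix of the same shape.
#' @export
binaryErode <- function(mask, cfg = morphConfig()) {
  m <- .checkMask(mask)
  hh <- cfg$height %/% 2L; hw <- cfg$width %/% 2L
  out <- matrix(1L, nrow(m), ncol(m))
  for (di in -hh:hh) for (dj in -hw:hw) {
    out <- pmin(out, .shiftMask(m, di, dj))
  }
  out
}

#' Binary closing (dilation followed by erosion)
#'
#' Merges foreground fragments separated by gaps narrower than the
#' structuring element. The dilation is carried out on a zero-padded
#' domain one SE radius wide, so that the composition stays extensive
#' (the input is a subset of the output), increasing, and idempotent on
#' the observed grid; eroding the unpadded dilation would clip
#' border-adjacent foreground instead.
#'
#' @inheritParams binaryDilate
#' @return 0/1 integer matrix of the same shape.
#' @examples
#' m <- matrix(0L, 3, 5); m[2, c(2, 4)] <- 1L
#' binaryClosing(m, morphConfig(3, 3))[2, ]  # one-cell gap is filled
#' @export
binaryClosing <- function(mask, cfg = morphConfig()) {
  m <- .checkMask(mask)
  hh <- cfg$height %/% 2L; hw <- cfg$width %/% 2L
  pad <- matrix(0L, nrow(m) + 2L * hh, ncol(m) + 2L * hw)
  pad[hh + seq_len(nrow(m)), hw + seq_len(ncol(m))] <- m
  cl <- binaryErode(binaryDilate(pad, cfg), cfg)
  cl[hh + seq_len(nrow(m)), hw + seq_len(ncol(m)), drop = FALSE]
}

#' Connected-component labeling
#'
#' Labels maximal sets of foreground cells mutually reachable through
#' 4- or 8-neighbor chains. Labels are assigned in row-major first-encounter
#' order (row 1 scanned left to right first), so labeling is deterministic.
#'
#' @inheritParams binaryDilate
#' @return list with `labels` (integer matrix, 0 = background),
#'   `nComponents`, and `areas` (cell count per label, in label order).
#' @examples
#' m <- matrix(0L, 3, 3); m[1, 1] <- 1L; m[2, 2] <- 1L
#' connectedComponents(m, morphConfig(connectivity = 8))$nComponents  # 1
#' connectedComponents(m, morphConfig(connectivity = 4))$nComponents  # 2
#' @export
connectedComponents <- function(mask, cfg = morphConfig()) {
  m <- .checkMask(mask)
  nr <- nrow(m); nc <- ncol(m)
  offsets <- if (cfg$connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    as.matrix(expand.grid(di = -1:1, dj = -1:1))[-5L, , drop = FALSE]
  }
  labels <- matrix(0L, nr, nc)
  k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (m[i, j] == 1L && labels[i, j] == 0L) {
      k <- k + 1L
      # iterative flood fill from (i, j)
      stack <- matrix(c(i, j), ncol = 2L)
      labels[i, j] <- k
      while (nrow(stack) > 0L) {
        cur <- stack[nrow(stack), ]
        stack <- stack[-nrow(stack), , drop = FALSE]
        ni <- cur[1] + offsets[, 1]; nj <- cur[2] + offsets[, 2]
        ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
        ni <- ni[ok]; nj <- nj[ok]
        idx <- (nj - 1L) * nr + ni
        hit <- m[idx] == 1L & labels[idx] == 0L
        if (any(hit)) {
          labels[idx[hit]] <- k
          stack <- rbind(stack, cbind(ni[hit], nj[hit]))
        }
      }
    }
  }
  areas <- if (k > 0L) tabulate(labels[labels > 0L], nbins = k) else integer()
  list(labels = labels, nComponents = k, areas = as.integer(areas))
}

#' Fill enclosed background holes
#'
#' Background regions not connected to the grid border are set to
#' foreground. The background complement is traversed with 4-connectivity,
#' the standard dual of 8-connected foreground.
#'
#' @inheritParams binaryDilate
#' @return 0/1 integer matrix of the same shape.
#' @export
fillHoles <- function(mask, cfg = morphConfig()) {
  m <- .checkMask(mask)
  nr <- nrow(m); nc <- ncol(m)
  if (nr == 0L || nc == 0L) return(m)
  reach <- matrix(FALSE, nr, nc)
  # seed: all background border cells
  seeds <- rbind(
    cbind(1L, seq_len(nc)), cbind(nr, seq_len(nc)),
    cbind(seq_len(nr), 1L), cbind(seq_len(nr), nc))
  seeds <- seeds[m[seeds] == 0L, , drop = FALSE]
  if (nrow(seeds)) {
    reach[seeds] <- TRUE
    stack <- seeds
    offs <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
    while (nrow(stack) > 0L) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      ni <- cur[1] + offs[, 1]; nj <- cur[2] + offs[, 2]
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      ni <- ni[ok]; nj <- nj[ok]
      idx <- (nj - 1L) * nr + ni
      hit <- m[idx] == 0L & !reach[idx]
      if (any(hit)) {
        reach[idx[hit]] <- TRUE
        stack <- rbind(stack, cbind(ni[hit], nj[hit]))
      }
    }
  }
  out <- m
  out[m == 0L & !reach] <- 1L
  out
}

#' Read / write 0/1 masks as CSV grids
#'
#' @param mask 0/1 matrix.
#' @param path file path.
#' @return `readMaskCSV` returns a 0/1 integer matrix.
#' @export
writeMaskCSV <- function(mask, path) {
  m <- .checkMask(mask)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeMaskCSV
#' @export
readMaskCSV <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  .checkMask(m)
}
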