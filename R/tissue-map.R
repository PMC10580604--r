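# Patch sampling, majority labeling, tissue-map assembly and map I/O.
# Coordinates are row-major (row, col); 0-based in files, 1-based in R.

#' Patch sampling configuration
#'
#' @param ratio sampling ratio in `(0, 1]`; default 0.05 (5% of the patch
#'   grid).
#' @param seed integer seed (NULL = current RNG state).
#' @param replace sample with replacement (default FALSE).
#' @return list of class `samplingConfig`.
#' @export
samplingConfig <- function(ratio = 0.05, seed = NULL, replace = FALSE) {
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  structure(list(ratio = ratio, seed = seed, replace = replace),
            class = "samplingConfig")
}

#' Sample patch positions from a slide grid
#'
#' Samples `max(1, round(ratio * N))` positions (round half up) uniformly,
#' without replacement by default, from the available positions of the patch
#' grid. Deterministic under the config seed.
#'
#' @param patch_source a [TissueMap-class], a label matrix, a logical
#'   availability matrix, or an integer vector `c(rows, cols)`.
#' @param cfg a [samplingConfig()].
#' @return data.frame with columns `row`, `col` (1-based).
#' @examples
#' nrow(samplePatches(c(10L, 10L), samplingConfig(0.05, seed = 1)))  # 5
#' @export
samplePatches <- function(patch_source, cfg = samplingConfig()) {
  stopifnot(inherits(cfg, "samplingConfig"))
  if (is(patch_source, "TissueMap")) patch_source <- as.matrix(patch_source)
  if (is.matrix(patch_source)) {
    avail <- if (is.logical(patch_source)) which(patch_source)
             else seq_len(length(patch_source))
    nr <- nrow(patch_source)
  } else {
    stopifnot(length(patch_source) == 2L)
    nr <- as.integer(patch_source[1])
    avail <- seq_len(nr * as.integer(patch_source[2]))
  }
  N <- length(avail)
  if (N == 0L) stop("patch source is empty")
  k <- max(1L, as.integer(.roundHalfUp(cfg$ratio * N)))
  k <- if (cfg$replace) k else min(k, N)
  idx <- if (N == 1L) rep(avail, k)
         else .withSeed(cfg$seed, sample(avail, k, replace = cfg$replace))
  data.frame(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}

#' Majority label of a patch region
#'
#' The patch label is the class covering the largest share of the region.
#' Ties are broken by the fixed order of `classSet` (the [tissueClasses()]
#' enumeration order by default).
#'
#' @param region character vector/matrix of sub-cell labels, or a named
#'   numeric vector of class proportions.
#' @param classSet class universe defining the tie-break order.
#' @return single class label.
#' @examples
#' majorityLabel(c("STR", "STR", "STR", "TUM", "TUM"))  # STR
#' majorityLabel(c(TUM = 0.5, LYM = 0.5))               # LYM (enum order)
#' @export
majorityLabel <- function(region, classSet = tissueClasses()) {
  if (is.numeric(region)) {
    if (is.null(names(region)) || !all(names(region) %in% classSet))
      stop("numeric region must be a named vector of class proportions")
    counts <- stats::setNames(numeric(length(classSet)), classSet)
    counts[names(region)] <- region
  } else {
    region <- as.vector(region)
    if (length(region) == 0L) stop("region is empty")
    if (!all(region %in% classSet)) stop("region contains invalid labels")
    counts <- table(factor(region, levels = classSet))
  }
  classSet[which.max(counts)]  # which.max takes the first (enum-order) max
}

#' Assemble a tissue map by classifying every grid position
#'
#' Requires a complete grid: one patch record per position. Each cell of the
#' returned map is the classifier's label for that patch.
#'
#' @param patches data.frame with columns `row`, `col` and (for trained
#'   classifiers) a list-column `img` of patch arrays; oracle classifiers
#'   only need positions.
#' @param nrow,ncol grid dimensions.
#' @param classifier a [PatchClassifier-class].
#' @param slideID slide identifier.
#' @param patchSize patch edge length in pixels.
#' @return a [TissueMap-class].
#' @export
buildTissueMap <- function(patches, nrow, ncol, classifier,
                           slideID = "slide", patchSize = 224L) {
  stopifnot(is.data.frame(patches), is(classifier, "PatchClassifier"))
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  have <- paste(patches$row, patches$col)
  need <- as.vector(outer(seq_len(nrow), seq_len(ncol), paste))
  missing <- setdiff(need, have)
  if (length(missing))
    stop(sprintf("missing patches at positions (row,col): %s",
                 paste(head(gsub(" ", ",", missing), 10L), collapse = "; ")))
  pred <- if (classifier@type == "oracle") {
    classifyPatches(classifier, patches[, intersect(
      c("row", "col", "slide_id"), names(patches)), drop = FALSE])
  } else {
    classifyPatches(classifier, patches$img)
  }
  labels <- matrix(NA_character_, nrow, ncol)
  labels[cbind(patches$row, patches$col)] <- pred$class
  TissueMap(labels, slideID = slideID, patchSize = patchSize,
            classSet = classifier@classes)
}

#' Write / read a tissue map as a CSV label grid
#'
#' Cells hold integer class codes (0-based index into the class set, in
#' [tissueClasses()] order for nine-class maps). A comment header records
#' the slide id, patch size, class set and optional config hash.
#'
#' @param map a [TissueMap-class].
#' @param path file path.
#' @param configHash optional provenance hash recorded in the header.
#' @return `readTissueMapCSV` returns a [TissueMap-class].
#' @export
writeTissueMapCSV <- function(map, path, configHash = NULL) {
  stopifnot(is(map, "TissueMap"))
  codes <- matrix(match(map@labels, map@classSet) - 1L, nrow(map@labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# slide_id=%s patch_size=%d classes=%s%s",
                     map@slideID, map@patchSize,
                     paste(map@classSet, collapse = "|"),
                     if (is.null(configHash)) ""
                     else paste0(" config_hash=", configHash)), con)
  utils::write.table(codes, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeTissueMapCSV
#' @export
readTissueMapCSV <- function(path) {
  hdr <- readLines(path, n = 1L)
  sid <- sub(".*slide_id=(\\S+).*", "\\1", hdr)
  psz <- as.integer(sub(".*patch_size=(\\d+).*", "\\1", hdr))
  cls <- strsplit(sub(".*classes=(\\S+).*", "\\1", hdr), "\\|")[[1]]
  codes <- as.matrix(utils::read.table(path, sep = ",", skip = 1L))
  dimnames(codes) <- NULL
  TissueMap(matrix(cls[codes + 1L], nrow(codes)), slideID = sid,
            patchSize = psz, classSet = cls)
}

# fixed, invertible display palette (one distinct 8-bit RGB per class)
.classPalette <- function(classSet) {
  pal <- c(ADI = "#F5E6C8", BACK = "#FFFFFF", DEB = "#8B5A2B",
           LYM = "#2040C0", MUC = "#B0E0E6", MUS = "#C08060",
           NORM = "#60A060", STR = "#C060A0", TUM = "#C02020",
           tumor = "#C02020", lymphocyte = "#2040C0", stroma = "#C060A0",
           other = "#D0D0D0")
  unname(pal[classSet])
}

#' Write / read a tissue map as a color-coded PNG
#'
#' Maps each class to a fixed distinct color (exactly invertible: reading
#' recovers the labels bit-for-bit).
#'
#' @inheritParams writeTissueMapCSV
#' @param classSet class set used when reading.
#' @param slideID,patchSize metadata to attach when reading.
#' @return `readTissueMapPNG` returns a [TissueMap-class].
#' @export
writeTissueMapPNG <- function(map, path) {
  stopifnot(is(map, "TissueMap"))
  pal <- .classPalette(map@classSet)
  rgb <- col2rgb(pal) / 255
  idx <- match(map@labels, map@classSet)
  img <- array(0, c(nrow(map@labels), ncol(map@labels), 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, idx], nrow(map@labels))
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname writeTissueMapPNG
#' @export
readTissueMapPNG <- function(path, classSet = tissueClasses(),
                             slideID = "slide", patchSize = 224L) {
  img <- png::readPNG(path)
  pal <- col2rgb(.classPalette(classSet))
  key <- paste(pal[1, ], pal[2, ], pal[3, ])
  obs <- paste(round(img[, , 1] * 255), round(img[, , 2] * 255),
               round(img[, , 3] * 255))
  idx <- match(obs, key)
  if (anyNA(idx)) stop("PNG contains colors outside the class palette")
  TissueMap(matrix(classSet[idx], dim(img)[1]), slideID = slideID,
            patchSize = patchSize, classSet = classSet)
}
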