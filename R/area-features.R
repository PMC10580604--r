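# The five tissue-area features set, computed on the four-class
# tissue map. Areas are measured in patch-count units on the closed masks
# (closing precedes component analysis, so filled gaps count toward area).

#' Names of the five tissue-area features, in canonical order
#'
#' @return character vector of length 5.
#' @export
areaFeatureNames <- function() {
  c("max_tumor_area", "lymphocyte_inside_tumor", "lymphocyte_around_tumor",
    "around_inside_ratio", "total_stroma_area")
}

# coerce TissueMap / 9-class matrix / 4-class matrix to a super-class matrix
.superMatrix <- function(x) {
  m <- if (is(x, "TissueMap")) as.matrix(x) else x
  stopifnot(is.matrix(m), is.character(m))
  if (all(m %in% superClasses())) m else superclassOf(m)
}

#' Area of the maximal tumor component
#'
#' The tumor mask is closed (5 x 5 rectangle by default), then labeled by
#' 8-connected component analysis; the largest component's area (on the
#' closed mask) is returned, 0 when the map holds no tumor.
#'
#' @param map a [TissueMap-class] or label matrix (nine- or four-class).
#' @param morph a [morphConfig()].
#' @return integer patch count.
#' @export
maxTumorArea <- function(map, morph = morphConfig()) {
  m <- .superMatrix(map)
  mask <- (m == "tumor") + 0L
  if (!any(mask == 1L)) return(0L)
  cc <- connectedComponents(binaryClosing(mask, morph), morph)
  if (cc$nComponents == 0L) 0L else max(cc$areas)
}

#' Lymphocyte counts inside and around the tumor region
#'
#' The tumor region is the hole-filled closing of the tumor mask, so a
#' lymphocyte fully surrounded by tumor counts as inside (the infiltration
#' reading). "Around" is the Chebyshev band of width `band` patches outside
#' the region. The two counts are disjoint by construction and never exceed
#' the total lymphocyte count.
#'
#' @inheritParams maxTumorArea
#' @param band around-band width in patches (Chebyshev distance, >= 1).
#' @return named integer vector `c(inside = , around = )`.
#' @export
lymphocytePartition <- function(map, morph = morphConfig(), band = 2L) {
  band <- as.integer(band)
  if (band < 1L) stop("band width must be >= 1")
  m <- .superMatrix(map)
  lym <- m == "lymphocyte"
  tum <- (m == "tumor") + 0L
  if (!any(tum == 1L)) {
    region <- matrix(0L, nrow(m), ncol(m))
  } else {
    region <- fillHoles(binaryClosing(tum, morph), morph)
  }
  # Chebyshev distance <= band from the region == dilation with a
  # (2*band+1) square SE
  bandSE <- morphConfig(2L * band + 1L, 2L * band + 1L, morph$connectivity)
  near <- binaryDilate(region, bandSE)
  inside <- sum(lym & region == 1L)
  around <- sum(lym & near == 1L & region == 0L)
  c(inside = as.integer(inside), around = as.integer(around))
}

#' Smoothed around/inside lymphocyte ratio
#'
#' Exactly `(around + 1) / (inside + 1)`; the +1 smoothing handles zero
#' lymphocyte counts (the (0, 0) case gives 1).
#'
#' @param inside,around non-negative lymphocyte patch counts.
#' @return positive real.
#' @examples
#' aroundInsideRatio(0, 0)  # 1
#' aroundInsideRatio(3, 7)  # 2
#' @export
aroundInsideRatio <- function(inside, around) {
  if (any(inside < 0) || any(around < 0)) stop("counts must be non-negative")
  (around + 1) / (inside + 1)
}

#' Total stroma area
#'
#' Count of foreground cells after closing the stroma mask (all components,
#' not just the largest). By closing extensivity the result is at least the
#' raw stroma count.
#'
#' @inheritParams maxTumorArea
#' @return integer patch count.
#' @export
totalStromaArea <- function(map, morph = morphConfig()) {
  m <- .superMatrix(map)
  mask <- (m == "stroma") + 0L
  if (!any(mask == 1L)) return(0L)
  sum(binaryClosing(mask, morph))
}

.areaFeatureRow <- function(m, morph, band) {
  lp <- lymphocytePartition(m, morph, band)
  data.frame(
    max_tumor_area = maxTumorArea(m, morph),
    lymphocyte_inside_tumor = lp[["inside"]],
    lymphocyte_around_tumor = lp[["around"]],
    around_inside_ratio = aroundInsideRatio(lp[["inside"]], lp[["around"]]),
    total_stroma_area = totalStromaArea(m, morph),
    tum_cells = sum(m == "tumor"),
    lym_cells = sum(m == "lymphocyte"),
    str_cells = sum(m == "stroma"))
}

#' @rdname extractAreaFeatures
#' @export
setMethod("extractAreaFeatures", "TissueMap",
  function(x, morph = morphConfig(), band = 2L, ...) {
    out <- .areaFeatureRow(.superMatrix(x), morph, band)
    cbind(data.frame(slide_id = slideID(x)), out)
  })

#' @rdname extractAreaFeatures
#' @export
setMethod("extractAreaFeatures", "matrix",
  function(x, morph = morphConfig(), band = 2L, ...) {
    .areaFeatureRow(.superMatrix(x), morph, band)
  })

#' Area features for every slide of a cohort
#'
#' @param cohort a [SyntheticCohort-class] or list of [TissueMap-class].
#' @param morph a [morphConfig()].
#' @param band around-band width in patches.
#' @return data.frame, one row per slide.
#' @export
cohortAreaFeatures <- function(cohort, morph = morphConfig(), band = 2L) {
  maps <- if (is(cohort, "SyntheticCohort")) tissueMaps(cohort) else cohort
  out <- do.call(rbind, lapply(maps, extractAreaFeatures,
                               morph = morph, band = band))
  rownames(out) <- NULL
  out
}
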