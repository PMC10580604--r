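#' Collapse a tissue map to the four super-classes
#'
#' TUM maps to `tumor`, LYM to `lymphocyte`, STR to `stroma`, and every other
#' class (including BACK and MUC) to `other`. Shape is preserved, so cell
#' counts are conserved: the super-class histogram of the result equals the
#' input class histogram pushed through the mapping.
#'
#' @param x a [TissueMap-class] or a character label matrix.
#' @param ... unused.
#' @return same type as `x`, with labels in [superClasses()].
#' @examples
#' tm <- TissueMap(matrix(c("TUM", "MUC", "STR", "LYM"), 2, 2))
#' as.matrix(toSuperclass(tm))
#' @export
setGeneric("toSuperclass", function(x, ...) standardGeneric("toSuperclass"))

#' Extract the five tissue-area features from a tissue map
#'
#' Computes, on the four-class tissue map, the area of the maximal tumor
#' component after closing, the lymphocyte counts inside and around the
#' (hole-filled, closed) tumor region, the smoothed ratio
#' `(around + 1) / (inside + 1)`, and the total stroma area after closing.
#' All areas are in patch-count units.
#'
#' @param x a [TissueMap-class] (nine- or four-class) or a label matrix.
#' @param morph a [morphConfig()]; default 5x5 rectangle, 8-connectivity.
#' @param band around-tumor band width in patches (Chebyshev distance),
#'   default 2.
#' @param ... unused.
#' @return one-row data.frame with columns `max_tumor_area`,
#'   `lymphocyte_inside_tumor`, `lymphocyte_around_tumor`,
#'   `around_inside_ratio`, `total_stroma_area`, plus raw audit counts
#'   `tum_cells`, `lym_cells`, `str_cells` (and `slide_id` for TissueMap
#'   input).
#' @export
setGeneric("extractAreaFeatures",
  function(x, morph = morphConfig(), band = 2L, ...)
    standardGeneric("extractAreaFeatures"))

#' Predict risk scores (higher = worse outcome)
#'
#' @param object a fitted [SurvModel-class] or [DeepConvSurv-class].
#' @param newdata feature matrix (SurvModel) or list of patch arrays
#'   (DeepConvSurv).
#' @param ... unused.
#' @return numeric vector of risk scores.
#' @export
setGeneric("predictRisk", function(object, newdata, ...)
  standardGeneric("predictRisk"))

#' Extract per-patch deep features from the last hidden layer
#'
#' @param object a [DeepConvSurv-class] extractor.
#' @param patches list of `edge x edge x 3` numeric arrays in `[0, 1]`.
#' @param ... unused.
#' @return numeric matrix, one row per patch, 32 columns by default.
#' @export
setGeneric("patchFeatures", function(object, patches, ...)
  standardGeneric("patchFeatures"))

#' Classify patches into tissue classes
#'
#' @param object a [PatchClassifier-class].
#' @param patches list of patch arrays; for oracle classifiers, a data.frame
#'   with `row`/`col` positions (plus `slide_id` when the oracle holds
#'   several slides) may be given instead.
#' @param ... unused.
#' @return data.frame with columns `class` and `confidence`.
#' @export
setGeneric("classifyPatches", function(object, patches, ...)
  standardGeneric("classifyPatches"))

#' @describeIn TissueMap-class accessor for the tissue map slide identifier
#' @param x a TissueMap.
#' @export
setGeneric("slideID", function(x) standardGeneric("slideID"))

#' @describeIn SyntheticCohort-class list of per-patient tissue maps
#' @param x a SyntheticCohort.
#' @export
setGeneric("tissueMaps", function(x) standardGeneric("tissueMaps"))

#' @describeIn SyntheticCohort-class planted ground-truth table
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @describeIn SyntheticCohort-class survival table (patient_id, time, event)
#' @export
setGeneric("survivalData", function(x) standardGeneric("survivalData"))
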