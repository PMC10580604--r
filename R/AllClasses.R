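#' The nine tissue classes
#'
#' The nine-class colorectal tissue taxonomy used throughout: adipose (ADI),
#' background (BACK), debris (DEB), lymphocytes (LYM), mucus (MUC), smooth
#' muscle (MUS), normal colon mucosa (NORM), cancer-associated stroma (STR)
#' and colorectal adenocarcinoma epithelium (TUM). BACK is the only class
#' excluded from feature extraction. The fixed order of this vector is also
#' the documented tie-break order for [majorityLabel()].
#'
#' @return character vector of the nine class codes.
#' @examples
#' tissueClasses()
#' @export
tissueClasses <- function() {
  c("ADI", "BACK", "DEB", "LYM", "MUC", "MUS", "NORM", "STR", "TUM")
}

#' The four super-classes of the tissue map
#'
#' Four-class grouping used by the area-feature stage: TUM maps to `tumor`,
#' LYM to `lymphocyte`, STR to `stroma`, and everything else (including BACK
#' and MUC) to `other`.
#'
#' @return character vector of the four super-class names.
#' @export
superClasses <- function() c("tumor", "lymphocyte", "stroma", "other")

#' Map nine-class labels to the four super-classes
#'
#' @param labels character vector or matrix of nine-class labels.
#' @return object of the same shape with values in [superClasses()].
#' @export
superclassOf <- function(labels) {
  out <- ifelse(labels == "TUM", "tumor",
         ifelse(labels == "LYM", "lymphocyte",
         ifelse(labels == "STR", "stroma", "other")))
  if (is.matrix(labels)) dim(out) <- dim(labels)
  out
}

#' TissueMap: per-slide grid of tissue-class labels
#'
#' A rectangular matrix assigning each patch position (row, col; 0-based in
#' all I/O, 1-based inside R) a tissue-class label, together with the patch
#' edge length in pixels and the slide identifier. The `classSet` slot lists
#' the admissible labels: the nine-class taxonomy for raw maps, the four
#' super-classes after [toSuperclass()].
#'
#' @slot labels character matrix of class labels.
#' @slot slideID length-one character.
#' @slot patchSize integer patch edge length in pixels.
#' @slot classSet character vector of admissible labels.
#' @export
setClass("TissueMap",
  representation(labels = "matrix", slideID = "character",
                 patchSize = "integer", classSet = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.character(object@labels))
      msg <- c(msg, "labels must be a character matrix")
    else if (!all(object@labels %in% object@classSet))
      msg <- c(msg, sprintf("invalid labels: %s",
        paste(unique(object@labels[!(object@labels %in% object@classSet)]),
              collapse = ", ")))
    if (length(object@slideID) != 1L) msg <- c(msg, "slideID must be length 1")
    if (length(object@patchSize) != 1L || object@patchSize < 1L)
      msg <- c(msg, "patchSize must be a positive integer")
    if (length(msg)) msg else TRUE
  })

#' Construct a TissueMap
#'
#' @param labels character matrix of class labels.
#' @param slideID slide identifier.
#' @param patchSize patch edge length in pixels.
#' @param classSet admissible label set; defaults to the nine classes.
#' @return a [TissueMap-class] object.
#' @examples
#' tm <- TissueMap(matrix("NORM", 3, 3), slideID = "s1", patchSize = 224L)
#' dim(tm)
#' @export
TissueMap <- function(labels, slideID = "slide", patchSize = 224L,
                      classSet = tissueClasses()) {
  new("TissueMap", labels = labels, slideID = as.character(slideID),
      patchSize = as.integer(patchSize), classSet = classSet)
}

#' SyntheticCohort: generated tissue maps, ground truth and survival
#'
#' Container for one synthetic cohort: one [TissueMap-class] per patient,
#' a ground-truth table of planted quantities (both raw recountable cell
#' counts and the feature-level truths the area-feature stage should
#' recover), a survival table (`patient_id`, `time`, `event`) and the
#' generating configuration.
#'
#' @slot maps list of [TissueMap-class], one per patient.
#' @slot groundTruth data.frame of planted quantities.
#' @slot survival data.frame with columns patient_id, time, event.
#' @slot config the [syntheticCohortConfig()] list used.
#' @export
setClass("SyntheticCohort",
  representation(maps = "list", groundTruth = "data.frame",
                 survival = "data.frame", config = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@maps) != nrow(object@groundTruth))
      msg <- c(msg, "one ground-truth row per map required")
    if (nrow(object@survival) &&
        !all(c("patient_id", "time", "event") %in% colnames(object@survival)))
      msg <- c(msg, "survival needs patient_id, time, event columns")
    if (length(msg)) msg else TRUE
  })

#' PatchClassifier: nine-class patch classifier handle
#'
#' Wraps either a trained softmax (cross-entropy) network over pooled pixel
#' features or the oracle path that returns generator ground-truth labels.
#'
#' @slot fit the underlying fitted model (or the truth map list for oracles).
#' @slot classes character vector of classes the model can emit.
#' @slot type `"nnet"` or `"oracle"`.
#' @slot pool integer pooling factor used to build pixel features.
#' @export
setClass("PatchClassifier",
  representation(fit = "ANY", classes = "character", type = "character",
                 pool = "integer"))

#' DeepConvSurv: convolutional Cox partial-likelihood feature extractor
#'
#' A small convolutional network (He-initialized, Adam-trained on the
#' negative log Cox partial likelihood of a scalar risk head) whose last
#' hidden fully connected layer (32 units by default) provides per-patch
#' histopathological features.
#'
#' @slot params list of layer weights.
#' @slot config the [deepConvSurvConfig()] used.
#' @slot tissue tissue class the extractor was trained on.
#' @slot trace numeric vector of per-epoch mean training losses.
#' @export
setClass("DeepConvSurv",
  representation(params = "list", config = "list", tissue = "character",
                 trace = "numeric"))

#' SurvModel: fitted survival model handle
#'
#' Uniform wrapper over the six supported survival models
#' (`lasso_cox`, `ridge_cox`, `en_cox`, `ssvm`, `rsf`, `gbrt`).
#' [predictRisk()] always returns risks oriented so that higher predicted
#' risk means worse predicted outcome.
#'
#' @slot name model name.
#' @slot fit underlying fitted object.
#' @slot center,scale feature standardization parameters.
#' @slot hyper hyperparameter list actually used.
#' @export
setClass("SurvModel",
  representation(name = "character", fit = "ANY", center = "numeric",
                 scale = "numeric", hyper = "list"))
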