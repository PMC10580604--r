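# S4 methods for TissueMap and SyntheticCohort

#' @describeIn TissueMap-class grid dimensions (rows, cols)
#' @param x a TissueMap.
#' @export
setMethod("dim", "TissueMap", function(x) dim(x@labels))

#' @describeIn TissueMap-class the underlying label matrix
#' @param ... unused.
#' @export
setMethod("as.matrix", "TissueMap", function(x, ...) x@labels)

#' @export
setMethod("slideID", "TissueMap", function(x) x@slideID)

#' @describeIn TissueMap-class label histogram over the class set
#' @export
setMethod("show", "TissueMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("TissueMap '%s': %d x %d patches of %d px\n",
              object@slideID, d[1], d[2], object@patchSize))
  counts <- tissueCounts(object)
  cat("  ", paste(sprintf("%s:%d", names(counts), counts), collapse = " "),
      "\n", sep = "")
})

#' Per-class cell counts of a tissue map
#'
#' @param x a [TissueMap-class] or a character label matrix.
#' @param classSet label universe (defaults to the map's own class set).
#' @return named integer vector over `classSet`.
#' @export
tissueCounts <- function(x, classSet = NULL) {
  if (is(x, "TissueMap")) {
    classSet <- classSet %||% x@classSet
    x <- x@labels
  } else {
    classSet <- classSet %||% tissueClasses()
  }
  tab <- table(factor(as.vector(x), levels = classSet))
  out <- as.integer(tab)
  names(out) <- classSet
  out
}

#' @rdname toSuperclass
#' @export
setMethod("toSuperclass", "TissueMap", function(x, ...) {
  new("TissueMap", labels = superclassOf(x@labels), slideID = x@slideID,
      patchSize = x@patchSize, classSet = superClasses())
})

#' @rdname toSuperclass
#' @export
setMethod("toSuperclass", "matrix", function(x, ...) superclassOf(x))

#' @export
setMethod("tissueMaps", "SyntheticCohort", function(x) x@maps)

#' @export
setMethod("groundTruth", "SyntheticCohort", function(x) x@groundTruth)

#' @export
setMethod("survivalData", "SyntheticCohort", function(x) x@survival)

#' @describeIn SyntheticCohort-class compact cohort summary
#' @param object a SyntheticCohort.
#' @export
setMethod("show", "SyntheticCohort", function(object) {
  n <- length(object@maps)
  ev <- if (nrow(object@survival)) sum(object@survival$event) else NA_integer_
  cat(sprintf("SyntheticCohort: %d patients, %s events", n, ev))
  if (n) {
    d <- dim(object@maps[[1]])
    cat(sprintf(", maps %d x %d", d[1], d[2]))
  }
  cat("\n")
})
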