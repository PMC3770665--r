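#' @name accessors
#' @title Accessors for restflow data classes
#' @description Slot-free access to the assay matrices, annotations, ground
#'   truth and provenance of [FlowExperiment-class] and
#'   [ExpressionProfile-class] objects, and to the sets/universe of a
#'   [GeneSets-class] collection.
#' @param x an object of the documented class.
#' @return `intensities()` and `detectionP()` return numeric matrices;
#'   `geneSymbols()` a character vector; `simTruth()` a `DataFrame` or `NULL`;
#'   `log2Expression()` a numeric matrix; `provenance()` a named integer
#'   vector of per-stage probe counts; `setList()` a named list;
#'   `setUniverse()` a character vector.
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "FlowExperiment", function(x) assay(x, "intensities"))

#' @rdname accessors
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))
#' @rdname accessors
#' @export
setMethod("detectionP", "FlowExperiment", function(x) assay(x, "detectionP"))

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname accessors
#' @export
setMethod("geneSymbols", "SummarizedExperiment", function(x) {
  setNames(rowData(x)$symbol, rownames(x))
})

#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setMethod("simTruth", "SummarizedExperiment", function(x) {
  cols <- intersect(c("true_x", "true_y", "true_xprime", "true_yprime",
                      "planted_set"), colnames(rowData(x)))
  if (length(cols) == 0L) return(NULL)
  rowData(x)[, cols, drop = FALSE]
})

#' @rdname accessors
#' @export
setGeneric("log2Expression", function(x) standardGeneric("log2Expression"))
#' @rdname accessors
#' @export
setMethod("log2Expression", "ExpressionProfile", function(x) assay(x, "log2expr"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "ExpressionProfile", function(x) {
  unlist(metadata(x)$provenance)
})

#' @rdname accessors
#' @export
setGeneric("setList", function(x) standardGeneric("setList"))
#' @rdname accessors
#' @export
setMethod("setList", "GeneSets", function(x) x@sets)

#' @rdname accessors
#' @export
setGeneric("setUniverse", function(x) standardGeneric("setUniverse"))
#' @rdname accessors
#' @export
setMethod("setUniverse", "GeneSets", function(x) x@universe)

setMethod("show", "GeneSets", function(object) {
  cat("GeneSets collection:", length(object@sets), "sets,",
      length(object@universe), "universe genes\n")
  n <- min(5L, length(object@sets))
  for (i in seq_len(n))
    cat(sprintf("  %s (%d genes)\n", names(object@sets)[i],
                length(object@sets[[i]])))
  if (length(object@sets) > n) cat("  ...\n")
})

setMethod("show", "FlowExperiment", function(object) {
  callNextMethod()
  det <- sum(apply(detectionP(object), 1L, min) < 0.01)
  cat(sprintf("detected probes (min p < 0.01): %d / %d\n", det, nrow(object)))
})
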