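#' FlowExperiment: six-condition probe-level intensity data
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two assays,
#' `intensities` (non-negative linear-scale probe intensities) and
#' `detectionP` (per-probe, per-sample detection p-values in \[0,1\]), six
#' columns in the fixed order NF0, NF1, RF0, RF1, CF0, CF1, and a `symbol`
#' column in `rowData`. Synthetic datasets additionally carry ground-truth
#' columns (`true_x`, `true_y`, `true_xprime`, `true_yprime`, `planted_set`)
#' in `rowData` and the generating [simConfig()] in `metadata(x)$simConfig`.
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [simulateFlowData()], [readFlowData()], [preprocessFlow()]
#' @aliases FlowExperiment
#' @exportClass FlowExperiment
setClass("FlowExperiment", contains = "SummarizedExperiment")

setValidity("FlowExperiment", function(object) {
  msg <- character()
  if (!all(c("intensities", "detectionP") %in% names(assays(object))))
    msg <- c(msg, "assays must include 'intensities' and 'detectionP'")
  if (ncol(object) != 6L || !identical(colnames(object), .CONDITIONS))
    msg <- c(msg, sprintf("columns must be exactly %s in that order",
                          paste(.CONDITIONS, collapse = ", ")))
  if (length(msg) == 0L) {
    ints <- assay(object, "intensities")
    dp <- assay(object, "detectionP")
    if (any(!is.finite(ints)) || any(ints < 0))
      msg <- c(msg, "intensities must be finite and >= 0")
    if (any(!is.finite(dp)) || any(dp < 0) || any(dp > 1))
      msg <- c(msg, "detection p-values must lie in [0, 1]")
    if (!"symbol" %in% colnames(rowData(object)))
      msg <- c(msg, "rowData must contain a 'symbol' column")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FlowExperiment
#'
#' @param intensities numeric probe x 6 matrix of non-negative linear-scale
#'   intensities; columns are reordered to the fixed condition order if named.
#' @param detectionP numeric matrix of detection p-values, same shape.
#' @param symbols character vector of gene symbols, one per probe; `NA`,
#'   empty, or [unannotatedPrefix()]-prefixed entries mark unannotated probes.
#' @param truth optional `DataFrame`/`data.frame` of ground-truth columns.
#' @param metadata optional list stored as object metadata.
#' @return A [FlowExperiment-class] object.
#' @examples
#' m <- matrix(100, nrow = 2, ncol = 6,
#'             dimnames = list(c("p1", "p2"), flowConditions()))
#' p <- matrix(0.001, nrow = 2, ncol = 6, dimnames = dimnames(m))
#' FlowExperiment(m, p, symbols = c("ACTB", "COX2"))
#' @export
FlowExperiment <- function(intensities, detectionP, symbols,
                           truth = NULL, metadata = list()) {
  intensities <- as.matrix(intensities)
  detectionP <- as.matrix(detectionP)
  if (!identical(dim(intensities), dim(detectionP)))
    stop("'intensities' and 'detectionP' must have the same dimensions")
  if (!is.null(colnames(intensities))) {
    if (!setequal(colnames(intensities), .CONDITIONS))
      stop("column names must be the six conditions ",
           paste(.CONDITIONS, collapse = ", "))
    intensities <- intensities[, .CONDITIONS, drop = FALSE]
    detectionP <- detectionP[, .CONDITIONS, drop = FALSE]
  } else {
    if (ncol(intensities) != 6L)
      stop("matrices must have six columns (", paste(.CONDITIONS, collapse = ", "), ")")
    colnames(intensities) <- colnames(detectionP) <- .CONDITIONS
  }
  if (length(symbols) != nrow(intensities))
    stop("'symbols' must have one entry per probe")
  rd <- DataFrame(symbol = as.character(symbols))
  if (!is.null(truth)) rd <- cbind(rd, DataFrame(truth))
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("probe%06d", seq_len(nrow(intensities)))
  rownames(detectionP) <- rownames(intensities)
  se <- SummarizedExperiment(
    assays = list(intensities = intensities, detectionP = detectionP),
    rowData = rd,
    colData = DataFrame(
      condition = .CONDITIONS,
      flow = sub("[01]$", "", .CONDITIONS),
      timepoint = as.integer(sub("^..", "", .CONDITIONS)),
      row.names = .CONDITIONS),
    metadata = metadata)
  new("FlowExperiment", se)
}

#' ExpressionProfile: preprocessed log2 expression for the six conditions
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a single `log2expr`
#' assay of filtered, floored, log2-transformed expression values, with the
#' six fixed condition columns. `metadata(x)$provenance` records the probe
#' count retained at each preprocessing stage (monotonically non-increasing).
#'
#' @seealso [preprocessFlow()], [flowRatios()]
#' @aliases ExpressionProfile
#' @exportClass ExpressionProfile
setClass("ExpressionProfile", contains = "SummarizedExperiment")

setValidity("ExpressionProfile", function(object) {
  msg <- character()
  if (!"log2expr" %in% names(assays(object)))
    msg <- c(msg, "assay 'log2expr' is required")
  if (ncol(object) != 6L || !identical(colnames(object), .CONDITIONS))
    msg <- c(msg, "columns must be the six fixed conditions")
  if (length(msg) == 0L && anyNA(assay(object, "log2expr")))
    msg <- c(msg, "log2expr must not contain missing values")
  prov <- metadata(object)$provenance
  if (!is.null(prov) && is.unsorted(rev(unlist(prov))))
    msg <- c(msg, "provenance counts must be non-increasing through stages")
  if (length(msg)) msg else TRUE
})

#' GeneSets: a named gene-set collection with its universe
#'
#' Gene sets are stored as a named list of unique, harmonized (upper-case)
#' gene symbols, all contained in the `universe` of analyzable genes. Used
#' for over-representation analysis; the universe should be the post-filter
#' analyzed gene list, not the whole array, so that over-representation
#' conditions on what could have been selected.
#'
#' @slot sets named list of character vectors (no empty sets, unique names).
#' @slot universe character vector of gene symbols.
#' @seealso [geneSets()], [readGmt()], [oraReport()]
#' @exportClass GeneSets
setClass("GeneSets", representation(sets = "list", universe = "character"))

setValidity("GeneSets", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "sets must have unique non-empty names")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "empty gene sets are not allowed")
  if (!all(unlist(object@sets) %in% object@universe))
    msg <- c(msg, "all set members must belong to the universe")
  if (length(msg)) msg else TRUE
})
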