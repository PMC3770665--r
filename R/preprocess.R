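#' Quantile-normalize an intensity matrix
#'
#' Forces every column to share the same value distribution: the sorted
#' values of each output column equal the row-wise mean of the column-sorted
#' input, and within-column rank order is preserved. Ties within a column
#' receive the mean of the reference values at their tied ranks (delegated
#' to [limma::normalizeQuantiles()] with `ties = TRUE`).
#'
#' @param x numeric probe x sample matrix; finite, non-negative, >= 2 columns.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  if (any(!is.finite(x))) stop("intensity matrix must be finite")
  if (any(x < 0)) stop("intensity matrix must be non-negative")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Floor intensities and transform to log2
#'
#' Raw intensities below `floor_value` are set to `floor_value` before
#' log2-transformation, so the minimum output is `log2(floor_value)`.
#' Flooring is idempotent in linear space.
#'
#' @param x numeric matrix (or vector) of finite linear-scale intensities.
#' @param floor_value positive flooring threshold (default 10).
#' @return `log2(pmax(x, floor_value))`, same shape as `x`.
#' @examples
#' floorLog2(c(5, 1024))  # log2(10), 10
#' @export
floorLog2 <- function(x, floor_value = 10) {
  if (length(floor_value) != 1L || !is.finite(floor_value) || floor_value <= 0)
    stop("'floor_value' must be a single positive number")
  if (any(!is.finite(x))) stop("intensities must be finite")
  log2(pmax(x, floor_value))
}

#' Detection filter
#'
#' Retains the probes whose detection p-value is strictly below `alpha` in
#' at least one sample, i.e. rows with `min(detection_p) < alpha`.
#'
#' @param x numeric probe x sample matrix (any value matrix to subset).
#' @param detection_p matrix of detection p-values, same shape as `x`.
#' @param alpha detection threshold (default 0.01, strict).
#' @return `x` restricted to the retained rows, with the retained count in
#'   attribute `"n_retained"`.
#' @examples
#' x <- matrix(1, 2, 6); p <- rbind(rep(0.02, 6), c(0.005, rep(0.5, 5)))
#' nrow(detectionFilter(x, p))  # 1
#' @export
detectionFilter <- function(x, detection_p, alpha = 0.01) {
  x <- as.matrix(x); detection_p <- as.matrix(detection_p)
  if (!identical(dim(x), dim(detection_p)))
    stop("'x' and 'detection_p' must have the same shape")
  keep <- apply(detection_p, 1L, min) < alpha
  out <- x[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  out
}

.isUnannotated <- function(symbols) {
  is.na(symbols) | !nzchar(symbols) | startsWith(symbols, .UNANNOTATED_PREFIX)
}

#' Annotation filter
#'
#' Drops probes whose gene symbol is missing, empty, or carries the reserved
#' [unannotatedPrefix()] marker (emulating unnamed RIKEN cDNA probes).
#'
#' @param x numeric probe x sample matrix.
#' @param symbols character vector, one symbol per row of `x`.
#' @return `x` restricted to annotated rows, with attribute `"n_retained"`.
#' @examples
#' x <- matrix(1, 3, 6)
#' nrow(annotationFilter(x, c("ACTB", NA, "COX2")))  # 2
#' @export
annotationFilter <- function(x, symbols) {
  x <- as.matrix(x)
  if (length(symbols) != nrow(x))
    stop("every row must have an annotation record")
  keep <- !.isUnannotated(as.character(symbols))
  out <- x[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Preprocess a six-condition FlowExperiment
#'
#' Runs the fixed preprocessing chain: quantile normalization, flooring,
#' log2 transformation, detection filtering (min p < `alpha` in >= 1 sample)
#' and annotation filtering, recording the probe count retained at each
#' stage. The filters are pure row-selections: retained values are unchanged.
#'
#' Cross-sample quantile normalization forces all columns onto a common
#' reference distribution and therefore perturbs individual probe values;
#' set `normalize = FALSE` for data already on a common scale (e.g.
#' noise-free simulations used for exact ground-truth recovery).
#'
#' @param x a [FlowExperiment-class].
#' @param normalize apply quantile normalization (default `TRUE`).
#' @param floor_value flooring threshold on the (normalized) linear scale.
#' @param alpha detection p-value threshold (strict).
#' @return An [ExpressionProfile-class] with assay `log2expr`, the surviving
#'   `rowData` columns, and `metadata(x)$provenance` counts
#'   (`probes`, `detected`, `annotated`).
#' @examples
#' fe <- simulateFlowData(simConfig(n_probes = 300, seed = 1))
#' ep <- preprocessFlow(fe)
#' provenance(ep)
#' @export
preprocessFlow <- function(x, normalize = TRUE, floor_value = 10, alpha = 0.01) {
  stopifnot(is(x, "FlowExperiment"))
  m <- intensities(x)
  if (normalize) m <- quantileNormalize(m)
  lg <- floorLog2(m, floor_value)

  keep_det <- apply(detectionP(x), 1L, min) < alpha
  lg1 <- lg[keep_det, , drop = FALSE]
  sym1 <- geneSymbols(x)[keep_det]
  keep_ann <- !.isUnannotated(sym1)
  lg2 <- lg1[keep_ann, , drop = FALSE]

  rd <- rowData(x)[keep_det, , drop = FALSE][keep_ann, , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(log2expr = lg2),
    rowData = rd,
    colData = colData(x),
    metadata = c(metadata(x)[setdiff(names(metadata(x)), "provenance")],
                 list(provenance = c(probes = nrow(x),
                                     detected = sum(keep_det),
                                     annotated = sum(keep_ann)))))
  new("ExpressionProfile", se)
}
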