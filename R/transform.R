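#' Flow/no-flow log2 ratios per time point
#'
#' For each gene, computes the log2 expression ratios of the two flow
#' regimes against no flow at each time point (differences of already-log2
#' expression): `x0 = CF0 - NF0`, `x1 = CF1 - NF1` (continuous flow) and
#' `y0 = RF0 - NF0`, `y1 = RF1 - NF1` (rest-inserted flow).
#'
#' @param x an [ExpressionProfile-class], or a numeric gene x 6 matrix of
#'   log2 expression with the condition columns of [flowConditions()].
#' @return A [S4Vectors::DataFrame] with columns `probe`, `symbol` (when
#'   available), `x0`, `x1`, `y0`, `y1`.
#' @examples
#' m <- matrix(c(8, 8.1, 8.4, 8.3, 8.2, 8.0), nrow = 1,
#'             dimnames = list("p1", flowConditions()))
#' flowRatios(m)
#' @export
flowRatios <- function(x) {
  if (is(x, "ExpressionProfile")) {
    m <- log2Expression(x)
    sym <- geneSymbols(x)
  } else {
    m <- as.matrix(x)
    sym <- NULL
  }
  if (!all(.CONDITIONS %in% colnames(m)))
    stop("missing condition column(s): ",
         paste(setdiff(.CONDITIONS, colnames(m)), collapse = ", "))
  out <- DataFrame(
    probe = if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else rownames(m),
    x0 = unname(m[, "CF0"] - m[, "NF0"]),
    x1 = unname(m[, "CF1"] - m[, "NF1"]),
    y0 = unname(m[, "RF0"] - m[, "NF0"]),
    y1 = unname(m[, "RF1"] - m[, "NF1"]))
  if (!is.null(sym)) out$symbol <- unname(sym)
  rownames(out) <- out$probe
  out
}

#' Time-averaged flow/no-flow ratios
#'
#' Averages the two time points of each regime: `x = (x0 + x1) / 2`,
#' `y = (y0 + y1) / 2`. For independent per-time-point noise this halves the
#' noise variance, focusing the analysis on sustained expression changes.
#'
#' @param ratios output of [flowRatios()] (needs columns x0, x1, y0, y1).
#' @return `ratios` with columns `x` and `y` appended.
#' @examples
#' r <- DataFrame(x0 = 0.2, x1 = -0.1, y0 = 0.4, y1 = 0.2)
#' timeAverage(r)$x  # 0.05
#' @export
timeAverage <- function(ratios) {
  need <- c("x0", "x1", "y0", "y1")
  if (!all(need %in% colnames(ratios)))
    stop("ratios must contain columns x0, x1, y0, y1")
  if (any(!is.finite(unlist(as.data.frame(ratios[, need])))))
    stop("ratios must be finite")
  ratios$x <- (ratios$x0 + ratios$x1) / 2
  ratios$y <- (ratios$y0 + ratios$y1) / 2
  ratios
}

#' Rotate (x, y) into the common/differential frame
#'
#' Rotates the time-averaged ratio coordinates by 45 degrees:
#' `x' = scale * (x + y)`, `y' = scale * (y - x)`. With the default unitary
#' scale `1/sqrt(2)` the rotation is an isometry (`x'^2 + y'^2 = x^2 + y^2`).
#' x' measures the expression change common to both flow regimes (distance
#' along the diagonal y = x); y' measures the differential change
#' attributable to rest insertion (signed distance from the diagonal), with
#' `y' > 0` meaning the rest-inserted response exceeds the continuous one.
#'
#' @param x,y numeric vectors of time-averaged log2 ratios.
#' @param scale rotation scale factor (default `1/sqrt(2)`, unitary).
#' @param inverse if `TRUE`, treats `x`, `y` as (x', y') and applies the
#'   inverse rotation, returning the original coordinates.
#' @return A two-column matrix (`xprime`, `yprime`; or `x`, `y` when
#'   `inverse = TRUE`).
#' @examples
#' rotateCoordinates(1, 1)   # (sqrt(2), 0)
#' rotateCoordinates(0, 1)   # (1, 1) / sqrt(2)
#' @export
rotateCoordinates <- function(x, y, scale = 1 / sqrt(2), inverse = FALSE) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  if (inverse) {
    cbind(x = (x - y) / (2 * scale), y = (x + y) / (2 * scale))
  } else {
    cbind(xprime = scale * (x + y), yprime = scale * (y - x))
  }
}

#' Per-gene perturbation profiles through the full transformation
#'
#' Convenience wrapper computing the complete per-gene table: per-time-point
#' ratios ([flowRatios()]), time averages ([timeAverage()]) and rotated
#' common/differential scores ([rotateCoordinates()]).
#'
#' @inheritParams flowRatios
#' @param scale rotation scale (see [rotateCoordinates()]).
#' @return A [S4Vectors::DataFrame] with columns `probe`, `symbol` (when
#'   available), `x0`, `x1`, `y0`, `y1`, `x`, `y`, `xprime`, `yprime`.
#' @examples
#' fe <- simulateFlowData(simConfig(n_probes = 300, seed = 1))
#' pp <- perturbationProfiles(preprocessFlow(fe))
#' head(pp)
#' @export
perturbationProfiles <- function(x, scale = 1 / sqrt(2)) {
  pp <- timeAverage(flowRatios(x))
  rot <- rotateCoordinates(pp$x, pp$y, scale = scale)
  pp$xprime <- rot[, "xprime"]
  pp$yprime <- rot[, "yprime"]
  pp
}

#' Geometry and variance summaries of the rotated profiles
#'
#' Summarizes the point cloud in the rotated frame the way the bounding
#' ellipse of the accessible expression space is measured: the axis-aligned
#' extents `xprime_max - xprime_min` and `yprime_max - yprime_min` (reported
#' both as full ranges and as their halves, since the ranges play the role
#' of the ellipse axes), their aspect ratio, and the pooled variances of the
#' time-averaged profiles (over x and y) and of the single-time-point
#' profiles (over x0, x1, y0, y1).
#'
#' @param profiles output of [perturbationProfiles()] (or any table with
#'   columns `x0`, `x1`, `y0`, `y1`, `x`, `y`, `xprime`, `yprime`), >= 1 gene.
#' @return A list with elements `n_genes`, `extent_xprime`, `extent_yprime`,
#'   `semi_extent_xprime`, `semi_extent_yprime`, `aspect_ratio` (`NA` when
#'   the y' extent is zero), `var_timeavg`, `var_single_timepoint`.
#' @examples
#' fe <- simulateFlowData(simConfig(n_probes = 300, seed = 1))
#' summarizeGeometry(perturbationProfiles(preprocessFlow(fe)))
#' @export
summarizeGeometry <- function(profiles) {
  if (nrow(profiles) < 1L) stop("at least one gene is required")
  ext_x <- max(profiles$xprime) - min(profiles$xprime)
  ext_y <- max(profiles$yprime) - min(profiles$yprime)
  list(n_genes = nrow(profiles),
       extent_xprime = ext_x,
       extent_yprime = ext_y,
       semi_extent_xprime = ext_x / 2,
       semi_extent_yprime = ext_y / 2,
       aspect_ratio = if (ext_y > 0) ext_x / ext_y else NA_real_,
       var_timeavg = if (nrow(profiles) > 1L)
         var(c(profiles$x, profiles$y)) else NA_real_,
       var_single_timepoint = if (nrow(profiles) > 1L)
         var(c(profiles$x0, profiles$x1, profiles$y0, profiles$y1)) else NA_real_)
}
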