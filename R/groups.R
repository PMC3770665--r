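#' Select up- and down-regulated signature groups from y'
#'
#' Group A contains the `ceiling(fraction * N)` genes with the largest
#' differential scores y' (most up-regulated by rest insertion); Group B the
#' `floor(fraction * N)` genes with the smallest y' (most down-regulated).
#' The ceiling/floor convention splits the two tails of an odd quota
#' deterministically (at N = 11,970 and fraction 0.01 it yields 120 and
#' 119). Membership is sign-restricted: Group A members must have y' > 0 and
#' Group B members y' < 0; an exhausted tail truncates the group with a
#' warning. Ties are broken by gene id.
#'
#' @param yprime numeric vector of differential scores.
#' @param genes gene identifiers (default `names(yprime)`).
#' @param fraction selection fraction in (0, 0.5] (default 0.01).
#' @return A list of class `SignatureGroups`: `group_a` and `group_b`
#'   (ordered most-extreme-first), `fraction`, `universe_size`.
#' @examples
#' yp <- c(a = 3, b = 2, c = 1, d = -1, e = -2, f = -3, g = 0, h = 0,
#'         i = 0, j = 0)
#' selectGroups(yp, fraction = 0.2)
#' @export
selectGroups <- function(yprime, genes = names(yprime), fraction = 0.01) {
  if (length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction > 0.5)
    stop("'fraction' must lie in (0, 0.5]")
  if (any(!is.finite(yprime))) stop("y' scores must be finite")
  n <- length(yprime)
  if (is.null(genes)) genes <- as.character(seq_len(n))
  if (length(genes) != n) stop("'genes' must match 'yprime' in length")
  if (n < 1 / fraction)
    stop("universe too small for the requested fraction")

  n_a <- as.integer(ceiling(fraction * n))
  n_b <- as.integer(floor(fraction * n))
  ord_a <- order(-yprime, genes)
  ord_b <- order(yprime, genes)
  pos <- ord_a[yprime[ord_a] > 0]
  neg <- ord_b[yprime[ord_b] < 0]
  if (length(pos) < n_a) {
    warning("positive tail exhausted: Group A truncated to ",
            length(pos), " genes")
    n_a <- length(pos)
  }
  if (length(neg) < n_b) {
    warning("negative tail exhausted: Group B truncated to ",
            length(neg), " genes")
    n_b <- length(neg)
  }
  structure(list(group_a = genes[pos[seq_len(n_a)]],
                 group_b = genes[neg[seq_len(n_b)]],
                 fraction = fraction,
                 universe_size = n),
            class = "SignatureGroups")
}

#' @export
print.SignatureGroups <- function(x, ...) {
  cat(sprintf(
    "SignatureGroups: |A| = %d (rest-up), |B| = %d (rest-down), top %.3g%% of %d genes\n",
    length(x$group_a), length(x$group_b), 100 * x$fraction, x$universe_size))
  invisible(x)
}

#' Group-size sensitivity sweep against gene-set enrichment
#'
#' Re-runs over-representation analysis for growing prefixes of the ranked
#' up- and down-regulated gene lists (default sizes 5, 10, ..., 200 in steps
#' of 5) and tracks how each gene set's BH-FDR responds to the group size,
#' reporting the first size at which a set becomes significant and the size
#' attaining its minimum FDR.
#'
#' @param ranked_up,ranked_down gene ids ranked most-extreme-first (e.g. the
#'   groups of [selectGroups()] computed at a generous fraction, or full
#'   rankings); must cover `max(sizes)`.
#' @param collection a [GeneSets-class] collection.
#' @param sizes strictly increasing group sizes (default `seq(5, 200, 5)`).
#' @param alpha FDR significance threshold (default 0.05).
#' @return A list of class `SweepResult`: `sizes`; `fdr_up` and `fdr_down`
#'   (size x set matrices of FDR values); `first_significant_up/_down` and
#'   `min_fdr_size_up/_down` (named per-set vectors, `NA` when never
#'   significant); `alpha`.
#' @examples
#' gs <- geneSets(list(S1 = c("g1", "g2")), universe = paste0("g", 1:100))
#' sw <- sensitivitySweep(paste0("g", 1:10), paste0("g", 91:100), gs,
#'                        sizes = c(5, 10))
#' sw$fdr_up
#' @export
sensitivitySweep <- function(ranked_up, ranked_down, collection,
                             sizes = seq(5L, 200L, by = 5L), alpha = 0.05) {
  stopifnot(is(collection, "GeneSets"))
  if (is.unsorted(sizes, strictly = TRUE))
    stop("'sizes' must be strictly increasing")
  if (max(sizes) > length(ranked_up) || max(sizes) > length(ranked_down))
    stop("ranked lists must cover max(sizes)")
  set_names <- names(setList(collection))
  fdr <- function(ranked) {
    m <- matrix(NA_real_, length(sizes), length(set_names),
                dimnames = list(as.character(sizes), set_names))
    for (i in seq_along(sizes)) {
      res <- oraReport(ranked[seq_len(sizes[i])], collection, alpha = alpha)
      m[i, res$set] <- res$q
    }
    m
  }
  fdr_up <- fdr(ranked_up)
  fdr_down <- fdr(ranked_down)
  firstSig <- function(m) apply(m, 2L, function(q) {
    i <- which(q < alpha)
    if (length(i)) sizes[min(i)] else NA_integer_
  })
  minSize <- function(m) apply(m, 2L, function(q) sizes[which.min(q)])
  structure(list(sizes = sizes, fdr_up = fdr_up, fdr_down = fdr_down,
                 first_significant_up = firstSig(fdr_up),
                 first_significant_down = firstSig(fdr_down),
                 min_fdr_size_up = minSize(fdr_up),
                 min_fdr_size_down = minSize(fdr_down),
                 alpha = alpha),
            class = "SweepResult")
}

#' @export
print.SweepResult <- function(x, ...) {
  cat(sprintf("SweepResult: sizes %d..%d (%d steps), %d gene sets\n",
              min(x$sizes), max(x$sizes), length(x$sizes), ncol(x$fdr_up)))
  cat("first significant size (up):",
      paste(names(x$first_significant_up), x$first_significant_up,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
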