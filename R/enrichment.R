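#' Build a harmonized gene-set collection
#'
#' Gene symbols are matched case-insensitively: sets and universe are
#' upper-cased and deduplicated, and set members absent from the universe
#' are dropped with a message reporting the count (or raise an error with
#' `on_unmatched = "error"`). Sets left empty after harmonization, and
#' duplicated set names, are errors.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param universe character vector of analyzable gene symbols. Use the
#'   post-filter analyzed gene list, not the full array, so that
#'   over-representation conditions on what could have been selected.
#' @param on_unmatched `"drop"` (default) or `"error"`.
#' @return A [GeneSets-class] object.
#' @examples
#' geneSets(list(S1 = c("Actb", "Cox2")), universe = c("ACTB", "COX2", "FOS"))
#' @export
geneSets <- function(sets, universe, on_unmatched = c("drop", "error")) {
  on_unmatched <- match.arg(on_unmatched)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicated gene set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  universe <- unique(toupper(universe))
  harmonized <- lapply(sets, function(g) unique(toupper(g)))
  n_dropped <- sum(vapply(harmonized, function(g) sum(!g %in% universe), 0L))
  if (n_dropped > 0L) {
    if (on_unmatched == "error")
      stop(n_dropped, " set member(s) absent from the universe")
    message(n_dropped, " set member(s) absent from the universe; dropped")
    harmonized <- lapply(harmonized, function(g) g[g %in% universe])
  }
  if (any(lengths(harmonized) == 0L))
    stop("set(s) empty after universe harmonization: ",
         paste(names(harmonized)[lengths(harmonized) == 0L], collapse = ", "))
  new("GeneSets", sets = harmonized, universe = universe)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing an overlap at least as large as the one seen
#' between a query gene list and a gene set, when the query is a uniform
#' draw from the universe: `P(X >= k)` for `X` hypergeometric with
#' universe size `N`, set size `m` and query size `n`.
#'
#' @param query character vector of query genes (non-empty, within universe).
#' @param gene_set character vector of set genes (within universe).
#' @param universe character vector of all analyzable genes.
#' @param on_unmatched `"drop"` query genes absent from the universe with a
#'   warning (default) or `"error"`.
#' @return The upper-tail p-value (in (0, 1]).
#' @examples
#' u <- paste0("g", 1:20)
#' hypergeomEnrich(u[1:5], u[1:5], u)  # 1 / choose(20, 5)
#' @export
hypergeomEnrich <- function(query, gene_set, universe,
                            on_unmatched = c("drop", "error")) {
  on_unmatched <- match.arg(on_unmatched)
  universe <- unique(universe)
  query <- unique(query)
  missing_q <- setdiff(query, universe)
  if (length(missing_q) > 0L) {
    if (on_unmatched == "error")
      stop(length(missing_q), " query gene(s) absent from the universe")
    warning(length(missing_q), " query gene(s) absent from the universe; dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop("query is empty (after harmonization)")
  gene_set <- intersect(unique(gene_set), universe)
  k <- length(intersect(query, gene_set))
  m <- length(gene_set)
  n <- length(query)
  N <- length(universe)
  phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1 (delegated to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Over-representation report for a gene-set collection
#'
#' Tests a query gene list against every set in a collection with the
#' upper-tail hypergeometric test and adjusts across sets with BH-FDR.
#' `mode` records whether the collection holds pathway membership lists or
#' perturbation-response signature lists; the arithmetic is identical, only
#' the interpretation differs.
#'
#' @param query character vector of query genes (matched case-insensitively).
#' @param collection a [GeneSets-class].
#' @param mode `"membership"` (default) or `"signature_overlap"`.
#' @param alpha FDR significance threshold for flagging (default 0.05).
#' @param on_unmatched handling of query genes outside the universe:
#'   `"drop"` with a warning (default) or `"error"`.
#' @return A `data.frame` sorted by q then p with columns `set`, `k`
#'   (overlap), `m` (set size), `n` (query size), `N` (universe size), `p`,
#'   `q`, `significant`, `overlap_genes` (comma-separated); `mode` and
#'   `alpha` are attached as attributes.
#' @examples
#' u <- paste0("g", 1:100)
#' gs <- geneSets(list(S1 = u[1:10], S2 = u[51:60]), universe = u)
#' oraReport(u[1:10], gs)
#' @export
oraReport <- function(query, collection, mode = c("membership", "signature_overlap"),
                      alpha = 0.05, on_unmatched = c("drop", "error")) {
  mode <- match.arg(mode)
  on_unmatched <- match.arg(on_unmatched)
  stopifnot(is(collection, "GeneSets"))
  universe <- setUniverse(collection)
  query <- unique(toupper(query))
  missing_q <- setdiff(query, universe)
  if (length(missing_q) > 0L) {
    if (on_unmatched == "error")
      stop(length(missing_q), " query gene(s) absent from the universe")
    warning(length(missing_q), " query gene(s) absent from the universe; dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0L)
    stop("query is empty after universe harmonization")
  sets <- setList(collection)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    ov <- intersect(query, sets[[nm]])
    k <- length(ov)
    m <- length(sets[[nm]])
    data.frame(set = nm, k = k, m = m, n = n, N = N,
               p = phyper(k - 1L, m, N - m, n, lower.tail = FALSE),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bhFdr(res$p)
  res$significant <- res$q < alpha
  res <- res[order(res$q, res$p, res$set),
             c("set", "k", "m", "n", "N", "p", "q", "significant",
               "overlap_genes")]
  rownames(res) <- NULL
  attr(res, "mode") <- mode
  attr(res, "alpha") <- alpha
  res
}
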