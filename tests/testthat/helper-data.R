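# shared fixture builders (all data generated in code)

# log2 expression matrix with the six fixed condition columns
log2Matrix <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- flowConditions()
  rownames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  m
}

# minimal FlowExperiment with constant detection p-values
tinyFlowExperiment <- function(intensities, p = 0.001, symbols = NULL) {
  if (is.null(colnames(intensities))) colnames(intensities) <- flowConditions()
  dp <- matrix(p, nrow(intensities), 6L, dimnames = dimnames(intensities))
  if (is.null(symbols)) symbols <- sprintf("G%03d", seq_len(nrow(intensities)))
  FlowExperiment(intensities, dp, symbols)
}

# brute-force upper-tail hypergeometric probability by enumerating all
# C(N, n) query draws; independent oracle for small N
enumHyper <- function(N, m, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= m)  # set = first m elements
  mean(hits >= k)
}

# hand step-up BH oracle
stepUpBH <- function(p) {
  mth <- length(p)
  o <- order(p)
  q <- p[o] * mth / seq_len(mth)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
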