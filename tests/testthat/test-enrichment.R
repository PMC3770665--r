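test_that("hypergeometric p-values match hand arithmetic", {
  u20 <- paste0("g", 1:20)
  expect_equal(hypergeomEnrich(u20[1:5], u20[1:5], u20), 1 / choose(20, 5))
  u10 <- paste0("g", 1:10)
  # N=10, m=2, n=2, k=1: 1 - C(8,2)/C(10,2)
  expect_equal(hypergeomEnrich(u10[c(1, 5)], u10[1:2], u10), 1 - 28 / 45)
  # zero overlap: P(X >= 0) is the certain event
  expect_equal(hypergeomEnrich(u10[5:6], u10[1:2], u10), 1)
})

test_that("hypergeometric tail agrees with exhaustive enumeration for N <= 12", {
  for (N in c(8, 10, 12)) {
    universe <- paste0("g", 1:N)
    for (m in c(2, 4)) for (n in c(3, 5)) {
      gene_set <- universe[seq_len(m)]
      for (k in max(0, m + n - N):min(m, n)) {
        query <- c(universe[seq_len(k)],
                   universe[m + seq_len(n - k)])
        expect_equal(hypergeomEnrich(query, gene_set, universe),
                     enumHyper(N, m, n, k), tolerance = 1e-12,
                     label = sprintf("N=%d m=%d n=%d k=%d", N, m, n, k))
      }
    }
  }
})

test_that("growing the overlap strictly decreases the p-value", {
  N <- 100; m <- 20; n <- 10
  p <- phyper((0:n) - 1, m, N - m, n, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
})

test_that("query genes outside the universe are dropped with a warning or rejected", {
  u <- paste0("g", 1:10)
  expect_warning(p <- hypergeomEnrich(c(u[1:2], "nope"), u[1:3], u), "dropped")
  expect_equal(p, hypergeomEnrich(u[1:2], u[1:3], u))
  expect_error(hypergeomEnrich(c(u[1], "nope"), u[1:3], u,
                               on_unmatched = "error"), "absent")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(21)
  p <- runif(40)
  expect_equal(bhFdr(p), stepUpBH(p))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gene-set collections harmonize case and validate structure", {
  gs <- geneSets(list(S1 = c("Actb", "cox2", "ACTB")),
                 universe = c("ACTB", "COX2", "FOS"))
  expect_equal(setList(gs)$S1, c("ACTB", "COX2"))
  expect_equal(setUniverse(gs), c("ACTB", "COX2", "FOS"))
  expect_message(
    gs2 <- geneSets(list(S1 = c("ACTB", "GHOST")), universe = c("ACTB")),
    "dropped")
  expect_equal(setList(gs2)$S1, "ACTB")
  expect_error(geneSets(list(S1 = "A", S1 = "B"), universe = c("A", "B")),
               "duplicated")
  expect_error(geneSets(list(S1 = "GHOST"), universe = "ACTB"), "empty")
})

test_that("ORA report ranks a planted overlap first at q < 0.05", {
  set.seed(31)
  universe <- sprintf("G%05d", 1:12000)
  planted <- sample(universe, 40)
  query <- c(planted[1:30], sample(setdiff(universe, planted), 90))
  decoys <- lapply(1:5, function(i) sample(universe, 40))
  names(decoys) <- paste0("DECOY", 1:5)
  gs <- geneSets(c(list(PLANTED = planted), decoys), universe = universe)
  res <- oraReport(query, gs)
  expect_equal(res$set[1], "PLANTED")
  expect_lt(res$q[1], 0.05)
  expect_equal(res$k[1], 30)
  # the uncorrected p is astronomically small (oracle bound)
  expect_lt(res$p[1], 1e-6)
  expect_equal(strsplit(res$overlap_genes[1], ",")[[1]], sort(planted[1:30]))

  # a disjoint set is capped at q = 1 and not flagged
  gs_dis <- geneSets(list(DIS = setdiff(universe, query)[1:40]),
                     universe = universe)
  res_dis <- oraReport(query, gs_dis)
  expect_false(res_dis$significant[1])
  expect_equal(res_dis$q[1], 1, tolerance = 0.2)
})

test_that("ORA null calibration: the false-positive rate approaches alpha", {
  # random 2000-gene queries against a fixed 2000-gene set in a 12000-gene
  # universe; overlap under the null is hypergeometric. Parameters chosen so
  # the discrete achievable tail probability nearest alpha is ~0.0499.
  set.seed(41)
  reps <- 10000
  k <- rhyper(reps, 2000, 10000, 2000)
  p <- phyper(k - 1, 2000, 10000, 2000, lower.tail = FALSE)
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(frac - 0.05), 2 * se)
})

test_that("ORA validates queries and duplicate handling", {
  u <- paste0("g", 1:50)
  gs <- geneSets(list(S1 = u[1:10]), universe = u)
  expect_error(suppressWarnings(oraReport("nope", gs)), "empty")
  expect_error(geneSets(setNames(list(u[1:3], u[4:6]), c("S", "S")),
                        universe = u), "duplicated")
})
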