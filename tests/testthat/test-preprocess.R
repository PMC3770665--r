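test_that("quantile normalization maps columns onto the mean-of-sorted reference", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantileNormalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))

  # identical columns are left unchanged
  m2 <- cbind(c(3, 1, 7), c(3, 1, 7))
  expect_equal(quantileNormalize(m2), m2)

  # columns that are permutations of one another all become permutations of
  # the shared reference distribution
  set.seed(1)
  v <- rexp(50)
  m3 <- cbind(v, sample(v), sample(v))
  out3 <- quantileNormalize(m3)
  for (j in 1:3) expect_equal(sort(out3[, j]), sort(v))
})

test_that("quantile-normalized columns share an identical sorted value vector", {
  set.seed(42)
  m <- matrix(rexp(600, rate = 1 / 50), ncol = 6)
  out <- quantileNormalize(m)
  ref <- sort(out[, 1])
  for (j in 2:6) expect_equal(sort(out[, j]), ref, tolerance = 1e-9)
  # within-column rank order is preserved
  for (j in 1:6) expect_equal(order(out[, j]), order(m[, j]))
})

test_that("quantile normalization validates its input", {
  expect_error(quantileNormalize(matrix(1:3, ncol = 1)), ">= 2 samples")
  expect_error(quantileNormalize(cbind(c(1, NA), c(1, 2))), "finite")
})

test_that("flooring and log2 transform behave as specified", {
  expect_equal(floorLog2(5), log2(10))
  expect_equal(floorLog2(1024), 10)
  # flooring is idempotent in linear space
  m <- matrix(c(0.5, 3, 10, 200), 2)
  expect_equal(floorLog2(pmax(m, 10)), floorLog2(m))
  expect_equal(min(floorLog2(m)), log2(10))
  expect_error(floorLog2(5, floor_value = 0), "positive")
  expect_error(floorLog2(5, floor_value = -1), "positive")
})

test_that("detection filter keeps exactly the rows crossing the threshold", {
  x <- matrix(seq_len(12), 2)
  p_all_fail <- matrix(0.02, 2, 6)
  expect_equal(nrow(detectionFilter(x, p_all_fail)), 0)

  p <- rbind(c(0.5, 0.5, 0.005, 0.5, 0.5, 0.5),
             rep(0.02, 6))
  kept <- detectionFilter(x, p)
  expect_equal(nrow(kept), 1)
  expect_equal(unname(kept[1, ]), x[1, ])  # values unchanged

  # the threshold is strict: p exactly at alpha does not pass
  p_edge <- matrix(0.01, 1, 6)
  expect_equal(nrow(detectionFilter(x[1, , drop = FALSE], p_edge)), 0)

  # toy 10-probe set with 4 passing rows
  set.seed(3)
  p10 <- matrix(runif(60, 0.02, 1), 10)
  p10[c(2, 5, 6, 9), 3] <- 0.001
  x10 <- matrix(rnorm(60), 10)
  out <- detectionFilter(x10, p10)
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "n_retained"), 4)
  expect_error(detectionFilter(x10, p10[1:5, ]), "same shape")
})

test_that("annotation filter drops unannotated probes only", {
  x <- matrix(rnorm(30), 5)
  sym <- c("ACTB", NA, "COX2", paste0(unannotatedPrefix(), "0001"), "FOS")
  out <- annotationFilter(x, sym)
  expect_equal(nrow(out), 3)
  expect_equal(out, x[c(1, 3, 5), ], ignore_attr = TRUE)

  # no unannotated probes: identity
  out2 <- annotationFilter(x, paste0("G", 1:5))
  expect_equal(out2, x, ignore_attr = TRUE)
  expect_error(annotationFilter(x, c("A", "B")), "annotation record")
})

test_that("preprocessing chain records monotone provenance and preserves values", {
  set.seed(10)
  n <- 200
  ints <- matrix(rexp(n * 6, 1 / 300), n, 6,
                 dimnames = list(sprintf("p%03d", 1:n), flowConditions()))
  dp <- matrix(runif(n * 6, 0.02, 1), n, 6, dimnames = dimnames(ints))
  dp[1:120, 1] <- 0.001
  sym <- sprintf("G%03d", 1:n)
  sym[1:30] <- paste0(unannotatedPrefix(), 1:30)
  fe <- FlowExperiment(ints, dp, sym)
  ep <- preprocessFlow(fe)
  prov <- provenance(ep)
  expect_equal(unname(prov), c(200, 120, 90))
  expect_false(is.unsorted(rev(prov)))
  expect_equal(nrow(ep), 90)
  # filters are row selections of the normalized/floored/logged matrix
  full <- floorLog2(quantileNormalize(ints))
  expect_equal(log2Expression(ep), full[rownames(ep), ])
})
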