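test_that("group sizes follow the ceiling/floor convention", {
  set.seed(1)
  n <- 11970
  yp <- rnorm(n)
  names(yp) <- sprintf("G%05d", seq_len(n))
  gr <- selectGroups(yp, fraction = 0.01)
  expect_length(gr$group_a, 120)
  expect_length(gr$group_b, 119)
  expect_equal(gr$universe_size, n)

  yp2 <- setNames(rnorm(100), paste0("g", 1:100))
  gr2 <- selectGroups(yp2, fraction = 0.01)
  expect_length(gr2$group_a, 1)
  expect_length(gr2$group_b, 1)
})

test_that("groups take the extreme tails with deterministic ties", {
  yp <- c(a = 3, b = 2, c = 1, d = -1, e = -2, f = -3,
          g = 0, h = 0, i = 0, j = 0)
  gr <- selectGroups(yp, fraction = 0.2)
  expect_equal(gr$group_a, c("a", "b"))
  expect_equal(gr$group_b, c("f", "e"))
  expect_length(intersect(gr$group_a, gr$group_b), 0)
  # every member's |y'| dominates every same-sign non-member
  expect_true(min(yp[gr$group_a]) > max(yp[setdiff(names(yp)[yp > 0], gr$group_a)]))
})

test_that("group membership is invariant to order-preserving transforms of y'", {
  set.seed(17)
  yp <- setNames(rnorm(500), sprintf("g%03d", 1:500))
  gr <- selectGroups(yp, fraction = 0.05)
  # a strictly increasing odd transform preserves ranks and signs
  gr2 <- selectGroups(sign(yp) * log1p(abs(yp)) * 3, names(yp), fraction = 0.05)
  expect_equal(gr2$group_a, gr$group_a)
  expect_equal(gr2$group_b, gr$group_b)
})

test_that("sign restriction truncates an exhausted tail with a warning", {
  yp <- setNames(c(5, 4, rep(-1, 98)), paste0("g", 1:100))
  expect_warning(gr <- selectGroups(yp, fraction = 0.05), "truncated")
  expect_equal(gr$group_a, c("g1", "g2"))
  expect_length(gr$group_b, 5)
  expect_error(selectGroups(yp, fraction = 0.6), "\\(0, 0.5\\]")
  expect_error(selectGroups(yp[1:10], fraction = 0.01), "too small")
})

test_that("the sensitivity sweep finds a planted set early and only there", {
  set.seed(23)
  universe <- sprintf("G%05d", 1:5000)
  planted <- sample(universe, 40)
  # ranked up-list: the 40 planted genes scattered within the top 50
  top50 <- c(planted, sample(setdiff(universe, planted), 10))[sample.int(50)]
  ranked_up <- c(top50, sample(setdiff(universe, top50), 150))
  ranked_down <- sample(setdiff(universe, ranked_up), 200)
  decoys <- lapply(1:4, function(i) sample(universe, 40))
  names(decoys) <- paste0("DECOY", 1:4)
  gs <- geneSets(c(list(PLANTED = planted), decoys), universe = universe)
  sw <- sensitivitySweep(ranked_up, ranked_down, gs)
  expect_lte(sw$first_significant_up[["PLANTED"]], 50)
  expect_lte(sw$min_fdr_size_up[["PLANTED"]], 60)
  # FDR is non-increasing while the prefix grows through the planted overlap
  fdr_planted <- sw$fdr_up[, "PLANTED"]
  grow <- sw$sizes <= 50
  expect_true(all(diff(fdr_planted[grow]) <= 1e-12))
  # a set disjoint from the top 200 never reaches significance
  dis <- geneSets(list(DIS = setdiff(universe, c(ranked_up, ranked_down))[1:40]),
                  universe = universe)
  sw_dis <- sensitivitySweep(ranked_up, ranked_down, dis)
  expect_true(all(sw_dis$fdr_up[, "DIS"] >= 0.05))
  expect_true(is.na(sw_dis$first_significant_up[["DIS"]]))
})

test_that("a single-size sweep equals one enrichment call", {
  set.seed(29)
  universe <- paste0("g", 1:500)
  gs <- geneSets(list(S1 = universe[1:30]), universe = universe)
  ranked <- sample(universe, 100)
  sw <- sensitivitySweep(ranked, rev(ranked), gs, sizes = 50L)
  single <- oraReport(ranked[1:50], gs)
  expect_equal(unname(sw$fdr_up[1, "S1"]), single$q[single$set == "S1"])
  expect_error(sensitivitySweep(ranked[1:10], ranked, gs, sizes = c(5, 50)),
               "cover")
})
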