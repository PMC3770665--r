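test_that("identical seeds give identical datasets; different seeds differ", {
  cfg7 <- simConfig(n_probes = 300, seed = 7)
  a <- simulateFlowData(cfg7)
  b <- simulateFlowData(cfg7)
  expect_identical(intensities(a), intensities(b))
  expect_identical(detectionP(a), detectionP(b))
  expect_identical(geneSymbols(a), geneSymbols(b))
  c <- simulateFlowData(simConfig(n_probes = 300, seed = 8))
  expect_false(identical(intensities(a), intensities(c)))
})

test_that("zero signal and zero noise collapse every ratio to zero", {
  cfg <- simConfig(n_probes = 100, frac_detected = 1, frac_unannotated = 0,
                   common_extent = 0, differential_extent = 0,
                   noise_var_per_timepoint = 0, seed = 1)
  pp <- perturbationProfiles(preprocessFlow(simulateFlowData(cfg),
                                            normalize = FALSE))
  expect_equal(max(abs(pp$x0)), 0)
  expect_equal(max(abs(pp$y1)), 0)
  expect_equal(max(abs(pp$yprime)), 0)
})

test_that("detection and annotation fractions are realized exactly", {
  cfg <- simConfig(n_probes = 5000, frac_detected = 0.4,
                   frac_unannotated = 0.25, seed = 2)
  fe <- simulateFlowData(cfg)
  detected <- apply(detectionP(fe), 1, min) < 0.01
  expect_equal(sum(detected), round(0.4 * 5000))
  sym_det <- geneSymbols(fe)[detected]
  expect_equal(sum(startsWith(sym_det, unannotatedPrefix())),
               round(0.25 * sum(detected)))
  # undetected probes never cross the detection threshold
  expect_true(all(detectionP(fe)[!detected, ] >= 0.01))
})

test_that("noise-free generation round-trips true scores through the pipeline", {
  cfg <- simConfig(n_probes = 2000, frac_detected = 1, frac_unannotated = 0,
                   noise_var_per_timepoint = 0, common_extent = 0.52,
                   differential_extent = 0.29, seed = 11)
  ep <- preprocessFlow(simulateFlowData(cfg), normalize = FALSE)
  pp <- perturbationProfiles(ep)
  tr <- simTruth(ep)
  expect_lt(max(abs(pp$xprime - tr$true_xprime)), 1e-6)
  expect_lt(max(abs(pp$yprime - tr$true_yprime)), 1e-6)
  expect_lt(max(abs(pp$x - tr$true_x)), 1e-6)
  # realized spans equal the configured extents exactly
  expect_equal(max(pp$xprime) - min(pp$xprime), 0.52, tolerance = 1e-9)
  expect_equal(max(pp$yprime) - min(pp$yprime), 0.29, tolerance = 1e-9)
})

test_that("time-averaging halves the noise variance of generated profiles", {
  cfg <- simConfig(n_probes = 20000, frac_detected = 1, frac_unannotated = 0,
                   common_extent = 0, differential_extent = 0,
                   noise_var_per_timepoint = 8e-3, seed = 3)
  pp <- perturbationProfiles(preprocessFlow(simulateFlowData(cfg),
                                            normalize = FALSE))
  g <- summarizeGeometry(pp)
  expect_equal(g$var_timeavg, 4e-3, tolerance = 0.1)
  expect_equal(g$var_single_timepoint, 8e-3, tolerance = 0.1)
  expect_equal(g$var_timeavg / g$var_single_timepoint, 0.5, tolerance = 0.1)
})

test_that("planted genes land in the requested differential tail", {
  cfg <- simConfig(
    n_probes = 2000, frac_detected = 1, frac_unannotated = 0,
    noise_var_per_timepoint = 1e-3,
    planted_sets = list(
      list(name = "UP", n_genes = 30, tail = "up", effect_size = 0.4),
      list(name = "DOWN", n_genes = 30, tail = "down", effect_size = 0.4)),
    seed = 4)
  ep <- preprocessFlow(simulateFlowData(cfg), normalize = FALSE)
  pp <- perturbationProfiles(ep)
  tr <- simTruth(ep)
  up <- which(!is.na(tr$planted_set) & tr$planted_set == "UP")
  dn <- which(!is.na(tr$planted_set) & tr$planted_set == "DOWN")
  expect_length(up, 30)
  expect_true(all(rank(-pp$yprime)[up] <= 40))
  expect_true(all(rank(pp$yprime)[dn] <= 40))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(n_probes = 0), "n_probes")
  expect_error(simConfig(frac_detected = 1.2), "fractions")
  expect_error(simConfig(common_extent = -1), "extents")
  expect_error(simConfig(noise_var_per_timepoint = NaN), "finite")
  cfg <- simConfig(n_probes = 50, frac_detected = 1, frac_unannotated = 0,
                   planted_sets = list(list(name = "BIG", n_genes = 100,
                                            tail = "up", effect_size = 1)),
                   seed = 1)
  expect_error(simulateFlowData(cfg), "larger than")
})
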