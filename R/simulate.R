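#' Simulation configuration
#'
#' Parameters for [simulateFlowData()]. Defaults emulate the statistical
#' structure of the six-condition bead-array study the analysis is designed
#' for: 45,281 probes of which 15,686 (34.6%) pass detection and 3,716 of
#' those lack usable gene symbols (leaving 11,970 analyzed genes); true
#' common (x') and differential (y') scores spanning 0.52 and 0.29 log2-ratio
#' units; and independent per-time-point log2-ratio noise whose variance is
#' halved by time-averaging.
#'
#' @param n_probes total number of probes on the simulated array.
#' @param frac_detected fraction of probes passing the detection filter
#'   (applied deterministically as `round(frac_detected * n_probes)`).
#' @param frac_unannotated fraction of detected probes carrying the
#'   [unannotatedPrefix()] marker instead of a gene symbol.
#' @param baseline_log2_mean,baseline_log2_sd log2-intensity baseline
#'   distribution of detected probes. The default mean (8, i.e. intensity
#'   256) keeps baselines well above the flooring threshold so flooring does
#'   not distort ratio recovery; undetected probes form a separate
#'   low-intensity stratum that exercises flooring.
#' @param baseline_log2_min lower truncation of the detected-probe baseline
#'   distribution (default 5, i.e. intensity 32), guaranteeing detected
#'   probes stay above the default flooring threshold of 10 even after
#'   flow-induced down-regulation.
#' @param common_extent target span (max minus min) of the true common
#'   scores x', in log2-ratio units. Draws are rescaled so the realized span
#'   equals this value exactly.
#' @param differential_extent target span of the true differential scores y'.
#' @param noise_var_per_timepoint variance of the independent noise added to
#'   each of the four per-time-point log2 ratios (x0, x1, y0, y1).
#' @param signal_shape shape of the bounded zero-midrange distribution the
#'   true scores are drawn from before rescaling: `"normal"` (light tails)
#'   or `"laplace"` (peaked, heavy tails).
#' @param planted_sets optional list of planted gene-set enrichments; each
#'   element is a list with fields `name`, `n_genes`, `tail` (`"up"` or
#'   `"down"`) and `effect_size` (log2-ratio units). Planted genes (always
#'   detected and annotated) get true y' placed in the requested tail.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return A validated list of class `simConfig`.
#' @examples
#' cfg <- simConfig(n_probes = 500, seed = 1)
#' @export
simConfig <- function(n_probes = 45281L,
                      frac_detected = 15686 / 45281,
                      frac_unannotated = 3716 / 15686,
                      baseline_log2_mean = 8,
                      baseline_log2_sd = 1.5,
                      baseline_log2_min = 5,
                      common_extent = 0.52,
                      differential_extent = 0.29,
                      noise_var_per_timepoint = 8e-3,
                      signal_shape = c("normal", "laplace"),
                      planted_sets = list(),
                      seed = 1L) {
  signal_shape <- match.arg(signal_shape)
  cfg <- list(n_probes = as.integer(n_probes),
              frac_detected = frac_detected,
              frac_unannotated = frac_unannotated,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              baseline_log2_min = baseline_log2_min,
              common_extent = common_extent,
              differential_extent = differential_extent,
              noise_var_per_timepoint = noise_var_per_timepoint,
              signal_shape = signal_shape,
              planted_sets = planted_sets,
              seed = as.integer(seed))
  num <- unlist(cfg[c("n_probes", "frac_detected", "frac_unannotated",
                      "baseline_log2_mean", "baseline_log2_sd",
                      "baseline_log2_min",
                      "common_extent", "differential_extent",
                      "noise_var_per_timepoint", "seed")])
  if (any(!is.finite(num)))
    stop("all numeric simConfig values must be finite")
  if (cfg$n_probes < 1L) stop("'n_probes' must be >= 1")
  if (cfg$frac_detected < 0 || cfg$frac_detected > 1 ||
      cfg$frac_unannotated < 0 || cfg$frac_unannotated > 1)
    stop("fractions must lie in [0, 1]")
  if (cfg$common_extent < 0 || cfg$differential_extent < 0)
    stop("extents must be >= 0")
  if (cfg$noise_var_per_timepoint < 0)
    stop("'noise_var_per_timepoint' must be >= 0")
  for (ps in cfg$planted_sets) {
    if (!all(c("name", "n_genes", "tail", "effect_size") %in% names(ps)))
      stop("each planted set needs fields name, n_genes, tail, effect_size")
    if (!ps$tail %in% c("up", "down"))
      stop("planted set tail must be 'up' or 'down'")
  }
  structure(cfg, class = "simConfig")
}

# draw n values from a symmetric zero-midrange distribution rescaled so the
# realized span (max - min) equals `extent` exactly
.drawScaled <- function(n, extent, shape) {
  if (extent <= 0 || n < 2L) return(rep(0, n))
  z <- switch(shape,
              normal = rnorm(n),
              laplace = sample(c(-1, 1), n, replace = TRUE) * rexp(n))
  z <- z - (max(z) + min(z)) / 2
  z * (extent / (max(z) - min(z)))
}

#' Generate a synthetic six-condition dataset
#'
#' Draws, for each detected gene, a true common score x' and differential
#' score y' from bounded zero-midrange distributions rescaled to the
#' configured spans, inverts the 45-degree rotation to obtain true
#' time-averaged ratios (x, y), adds independent per-time-point noise to get
#' (x0, x1, y0, y1), and emits linear-scale intensities
#' `NFt = 2^b`, `CFt = 2^(b + xt)`, `RFt = 2^(b + yt)` around a per-gene
#' baseline b. Undetected probes form a low-intensity stratum with all
#' detection p-values >= 0.01; a configurable share of detected probes is
#' unannotated. Planted-set genes receive differential effects placing them
#' in the requested y' tail, recorded in the ground truth.
#'
#' @param config a [simConfig()] object.
#' @return A [FlowExperiment-class] with ground-truth columns in `rowData`
#'   and the configuration in `metadata(x)$simConfig`.
#' @examples
#' fe <- simulateFlowData(simConfig(n_probes = 200, seed = 7))
#' fe
#' @export
simulateFlowData <- function(config = simConfig()) {
  if (!inherits(config, "simConfig")) config <- do.call(simConfig, config)
  set.seed(config$seed)
  n <- config$n_probes
  n_det <- round(config$frac_detected * n)
  det_idx <- sort(sample.int(n, n_det))
  is_det <- logical(n); is_det[det_idx] <- TRUE

  probe_ids <- sprintf("ILM%06d", seq_len(n))
  symbols <- sprintf("GENE%06d", seq_len(n))
  # unannotated share, applied separately within detected and undetected
  # strata so the detected-stratum accounting is exact
  n_unann_det <- round(config$frac_unannotated * n_det)
  unann <- c(sample(which(is_det), n_unann_det),
             sample(which(!is_det), round(config$frac_unannotated * (n - n_det))))
  symbols[unann] <- sprintf("%s%06d", .UNANNOTATED_PREFIX, unann)

  # true rotated-frame scores for detected genes
  xprime <- yprime <- rep(NA_real_, n)
  xprime[det_idx] <- .drawScaled(n_det, config$common_extent, config$signal_shape)
  yprime[det_idx] <- .drawScaled(n_det, config$differential_extent, config$signal_shape)

  planted <- rep(NA_character_, n)
  pool <- setdiff(det_idx, unann)
  for (ps in config$planted_sets) {
    if (ps$n_genes > length(pool))
      stop("planted set '", ps$name,
           "' is larger than the available detected, annotated gene count")
    gi <- sample(pool, ps$n_genes)
    pool <- setdiff(pool, gi)
    sgn <- if (ps$tail == "up") 1 else -1
    yprime[gi] <- sgn * ps$effect_size * runif(ps$n_genes, 0.9, 1.1)
    planted[gi] <- ps$name
  }

  # invert the unitary 45-degree rotation to the (x, y) ratio frame
  x <- (xprime - yprime) / sqrt(2)
  y <- (xprime + yprime) / sqrt(2)

  sdn <- sqrt(config$noise_var_per_timepoint)
  x0 <- x + rnorm(n, 0, sdn); x1 <- x + rnorm(n, 0, sdn)
  y0 <- y + rnorm(n, 0, sdn); y1 <- y + rnorm(n, 0, sdn)

  # truncated-normal baselines: detected probes never approach the floor
  plo <- pnorm(config$baseline_log2_min, config$baseline_log2_mean,
               config$baseline_log2_sd)
  b <- qnorm(runif(n, plo, 1), config$baseline_log2_mean,
             config$baseline_log2_sd)
  ints <- matrix(0, n, 6L, dimnames = list(probe_ids, .CONDITIONS))
  ints[det_idx, "NF0"] <- 2^b[det_idx]
  ints[det_idx, "NF1"] <- 2^b[det_idx]
  ints[det_idx, "CF0"] <- 2^(b[det_idx] + x0[det_idx])
  ints[det_idx, "CF1"] <- 2^(b[det_idx] + x1[det_idx])
  ints[det_idx, "RF0"] <- 2^(b[det_idx] + y0[det_idx])
  ints[det_idx, "RF1"] <- 2^(b[det_idx] + y1[det_idx])
  # undetected probes: low-intensity background stratum (exercises flooring)
  n_und <- n - n_det
  if (n_und > 0L)
    ints[!is_det, ] <- 2^matrix(rnorm(n_und * 6L, 3, 1), n_und, 6L)

  dp <- matrix(runif(n * 6L), n, 6L, dimnames = dimnames(ints))
  if (n_und > 0L)
    dp[!is_det, ] <- matrix(runif(n_und * 6L, 0.05, 1), n_und, 6L)
  # detected probes cross the threshold in exactly >= 1 random sample
  hit <- sample.int(6L, n_det, replace = TRUE)
  dp[cbind(det_idx, hit)] <- runif(n_det, 0, 0.0099)

  # undetected probes carry NA truth (their xprime/yprime were never drawn)
  truth <- DataFrame(true_x = x, true_y = y,
                     true_xprime = xprime, true_yprime = yprime,
                     planted_set = planted)
  FlowExperiment(ints, dp, symbols, truth = truth,
                 metadata = list(simConfig = unclass(config)))
}
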