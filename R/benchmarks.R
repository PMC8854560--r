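# Ground-truth validation battery. Each eval_* function generates synthetic
# scenes under the package's standard study conditions, runs the real
# pipeline on them, and measures recovery of the planted quantities. The
# same functions back the test suite and the reproduction script.

bench_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(99999999L, n)
}

#' Per-spine count recovery on synthetic scenes
#'
#' Generates scenes of GFP-filled heads with 1--4 planted scaffold
#' nanomodules (>= 250 nm apart, high SNR), detects clusters with both
#' segmentation paths and counts them per truth-seeded spine ROI.
#'
#' @param n_spines total spines to accumulate (default 200).
#' @param seed RNG seed.
#' @param spines_per_scene spines per generated field (default 8).
#' @return list: `threshold` and `seeded` exact-count recovery fractions,
#'   `agreement` (fraction of spines where the two paths agree), `n`.
#' @export
eval_count_recovery <- function(n_spines = 200L, seed = 1L,
                                spines_per_scene = 8L) {
  n_scenes <- ceiling(n_spines / spines_per_scene)
  seeds <- bench_seeds(seed, n_scenes)
  chs <- default_channel_specs()
  chs <- chs[chs$label %in% c("GFP", "PSD95"), ]
  ok_thr <- ok_seed <- agree <- logical(0)
  for (s in seq_len(n_scenes)) {
    spec <- scene_spec(
      field_size_px = c(448L, 448L), n_sections = 9L,
      n_spines = spines_per_scene, channel_specs = chs,
      offset_model = default_offset_model()[0, ],
      max_modules_per_spine = 4L, seed = seeds[s]
    )
    sc <- generate_scene(spec)
    rois <- roi_from_truth(sc$truth, sc$stack)
    tr <- sc$truth$clusters[sc$truth$clusters$channel == "PSD95", ]
    planted <- tabulate(tr$spine_id, nbins = nrow(rois$info))
    cnt <- function(cl) {
      a <- assign_to_spines(cl, rois, "fully_within")
      tabulate(a$spine_id[!is.na(a$spine_id)], nbins = nrow(rois$info))
    }
    c_thr <- cnt(detect_clusters(sc$stack, "PSD95"))
    c_sd <- cnt(segment_seeded(sc$stack, "PSD95"))
    ok_thr <- c(ok_thr, c_thr == planted)
    ok_seed <- c(ok_seed, c_sd == planted)
    agree <- c(agree, c_thr == c_sd)
  }
  list(
    threshold = mean(ok_thr), seeded = mean(ok_seed),
    agreement = mean(agree), n = length(ok_thr)
  )
}

#' Distance-measurement calibration against planted offsets
#'
#' Pair fields with receptor clusters laterally offset 150--200 nm from
#' scaffold clusters; both channels segmented with the seeded path and the
#' colocalized center-to-center distances compared to the planted offsets.
#'
#' @param n_pairs planted pairs (default 500).
#' @param seed RNG seed.
#' @return list: `bias_nm` (mean signed error), `mae_nm`, `n_measured`.
#' @export
eval_distance_calibration <- function(n_pairs = 500L, seed = 1L) {
  pf <- simulate_pair_field(n_pairs, seed = bench_seeds(seed, 1))
  ps <- segment_seeded(pf$stack, "PSD95")
  rc <- segment_seeded(pf$stack, "GluA2")
  d <- center_to_center(rc, ps, "colocalized_only", coloc_mode = "distance")
  tr <- pf$truth$clusters[pf$truth$clusters$channel == "GluA2", ]
  j <- apply(
    sqrt(outer(rc$x_nm, tr$x_nm, "-")^2 + outer(rc$y_nm, tr$y_nm, "-")^2),
    1, which.min
  )
  planted <- pf$truth$pairs$distance_nm[match(tr$id[j], pf$truth$pairs$id_a)]
  pl <- planted[match(d$id_a, rc$id)]
  err <- d$distance_nm - pl
  list(bias_nm = mean(err), mae_nm = mean(abs(err)), n_measured = nrow(d))
}

#' Recovery of a small between-channel offset difference
#'
#' Replicate scenes carry two receptor channels whose planted lateral
#' offset distributions differ by `delta_nm` in mean. Each replicate is
#' segmented, both receptor-to-scaffold distance samples are measured, and
#' the measured means plus a two-tailed K-S comparison decide whether the
#' planted ordering was recovered.
#'
#' @param n_reps replicate scenes (default 100).
#' @param n_pairs pairs per channel per scene (default 500).
#' @param delta_nm planted mean offset difference (default 13).
#' @param alpha K-S rejection level (default 0.01).
#' @param seed RNG seed.
#' @return list: `ordering_rate`, `ks_rejection_rate`,
#'   `mean_measured_delta_nm`, `n_reps`.
#' @export
eval_offset_ordering <- function(n_reps = 100L, n_pairs = 500L,
                                 delta_nm = 13, alpha = 0.01, seed = 1L) {
  seeds <- bench_seeds(seed, n_reps)
  ordered <- rejected <- logical(n_reps)
  deltas <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    pf <- simulate_pair_field(
      n_pairs,
      receptor_offsets = list(RecA = c(150, 200),
                              RecB = c(150 + delta_nm, 200 + delta_nm)),
      seed = seeds[r], grid_px = 28L, n_sections = 6L
    )
    ps <- segment_seeded(pf$stack, "PSD95")
    da <- center_to_center(segment_seeded(pf$stack, "RecA"), ps,
                           "colocalized_only", coloc_mode = "distance")
    db <- center_to_center(segment_seeded(pf$stack, "RecB"), ps,
                           "colocalized_only", coloc_mode = "distance")
    ordered[r] <- mean(db$distance_nm) > mean(da$distance_nm)
    rejected[r] <- ks_compare(da$distance_nm, db$distance_nm)$p < alpha
    deltas[r] <- mean(db$distance_nm) - mean(da$distance_nm)
  }
  list(
    ordering_rate = mean(ordered),
    ks_rejection_rate = mean(rejected),
    mean_measured_delta_nm = mean(deltas),
    n_reps = n_reps
  )
}

#' Null calibration and power of the statistical operators
#'
#' Monte-Carlo rejection rates at alpha = 0.05 under the null for the
#' count-distribution comparison (curve-fit F test and multinomial LRT),
#' the ANCOVA homogeneity-of-slopes test and the one-way ANOVA omnibus,
#' plus ANCOVA power for a slope contrast of 2.3 vs 1.0 at per-group
#' R^2 of about 0.3, n = 150 per group.
#'
#' @param n_reps Monte-Carlo replicates for the null rates (default 2000).
#' @param n_power replicates for the power estimate (default 200).
#' @param seed RNG seed.
#' @return list of rejection rates and the ANCOVA power.
#' @export
eval_stat_calibration <- function(n_reps = 2000L, n_power = 200L, seed = 1L) {
  sds <- bench_seeds(seed, 2)
  area_dist <- list(meanlog = log(0.6), sdlog = 0.5, min = 0.1, max = 2)
  noise_for <- function(slope, a) {
    slope * stats::sd(a) * sqrt(1 / 0.3 - 1)
  }
  set.seed(sds[1])
  cnt_g <- cnt_m <- anc <- anv <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    counts <- pmax(0, round(stats::rnorm(160, 2, 1)))
    grp <- rep(c("a", "b"), each = 80)
    cnt_g[i] <- fit_count_distributions(counts, grp)$p < 0.05
    cnt_m[i] <- fit_count_distributions(counts, grp,
                                        method = "multinomial")$p < 0.05
    a <- rlnorm_trunc(300, area_dist)
    y <- 2.3 * a + stats::rnorm(300, 0, noise_for(2.3, a))
    anc[i] <- ancova_slopes(a, y, rep(c("a", "b"), each = 150))$p < 0.05
    v <- stats::rnorm(90)
    anv[i] <- anova_tukey(v, rep(c("a", "b", "c"), each = 30))$p < 0.05
  }
  set.seed(sds[2])
  pow <- logical(n_power)
  for (i in seq_len(n_power)) {
    a1 <- rlnorm_trunc(150, area_dist)
    a2 <- rlnorm_trunc(150, area_dist)
    y1 <- 2.3 * a1 + stats::rnorm(150, 0, noise_for(2.3, a1))
    y2 <- 1.0 * a2 + stats::rnorm(150, 0, noise_for(1.0, a2))
    pow[i] <- ancova_slopes(c(a1, a2), c(y1, y2),
                            rep(c("a", "b"), each = 150))$p < 0.05
  }
  list(
    count_fit_null_rejection = mean(cnt_g),
    count_fit_multinomial_null_rejection = mean(cnt_m),
    ancova_null_rejection = mean(anc),
    anova_null_rejection = mean(anv),
    ancova_power = mean(pow),
    n_reps = n_reps
  )
}

#' Coefficient recovery for the two-subunit spine-size model
#'
#' Spines containing both cluster types are simulated from
#' `area = 0.417 nA + 0.26 nB + 0.53 + noise` (n = 110) and refitted; a
#' replicate counts as recovered for a coefficient when the estimate lies
#' within two standard errors of the generative value.
#'
#' @param n_reps replicates (default 200).
#' @param n_spines spines per replicate (default 110).
#' @param seed RNG seed.
#' @return list: per-coefficient recovery rates, their minimum, and the
#'   mean fitted coefficients.
#' @export
eval_multivar_recovery <- function(n_reps = 200L, n_spines = 110L,
                                   seed = 1L) {
  set.seed(bench_seeds(seed, 1))
  b <- c(nA = 0.417, nB = 0.26, intercept = 0.53)
  hit <- matrix(FALSE, n_reps, 3,
                dimnames = list(NULL, c("nA", "nB", "intercept")))
  est <- matrix(0, n_reps, 3)
  for (i in seq_len(n_reps)) {
    nA <- 1 + stats::rpois(n_spines, 1.0)
    nB <- 1 + stats::rpois(n_spines, 0.8)
    area <- b["nA"] * nA + b["nB"] * nB + b["intercept"] +
      stats::rnorm(n_spines, 0, 0.6)
    f <- multivar_size_regression(area, nA, nB)
    co <- f$coefficients
    hit[i, "nA"] <- abs(co$estimate[1] - b["nA"]) <= 2 * co$se[1]
    hit[i, "nB"] <- abs(co$estimate[2] - b["nB"]) <= 2 * co$se[2]
    hit[i, "intercept"] <- abs(f$intercept - b["intercept"]) <=
      2 * f$intercept_se
    est[i, ] <- c(co$estimate, f$intercept)
  }
  rates <- colMeans(hit)
  list(
    rate_nA = rates[["nA"]], rate_nB = rates[["nB"]],
    rate_intercept = rates[["intercept"]],
    min_rate = min(rates),
    mean_estimates = colMeans(est),
    n_reps = n_reps
  )
}

#' Optical calibration operator checks
#'
#' FWHM of an exact Gaussian profile against the closed form, bead
#' peak-to-peak recovery at 50 nm (single color) and 70 nm (dual color)
#' spacings, and recovery of a planted 30 nm chromatic shift.
#'
#' @param seed RNG seed.
#' @return list of measured values (nm) and their planted references.
#' @export
eval_calibration_operators <- function(seed = 1L) {
  sds <- bench_seeds(seed, 4)
  x <- seq(0, 400, by = 5)
  prof <- 100 * exp(-(x - 200)^2 / (2 * 21.23^2)) + 3
  fwhm <- as.numeric(fwhm_from_profile(prof, 5))
  psf <- list(fwhm_xy_nm = 50, fwhm_z_nm = 300)
  p2p <- mean(measure_bead_pairs(
    simulate_bead_field(50, 10L, psf, seed = sds[1]), 2L
  ))
  p2p_dual <- mean(measure_bead_pairs(
    simulate_bead_field(70, 10L, psf, seed = sds[2], dual_color = TRUE), 3L
  ))
  shift <- chromatic_shift_check(30, psf, seed = sds[3])
  list(
    fwhm_nm = fwhm, fwhm_expected_nm = 2.3548 * 21.23,
    bead_p2p_nm = p2p, bead_spacing_nm = 50,
    dual_p2p_nm = p2p_dual, dual_spacing_nm = 70,
    chromatic_shift_nm = shift, chromatic_planted_nm = 30
  )
}

#' Potentiation-classifier agreement with generative labels
#'
#' @param n_spines spines per condition (default 100).
#' @param seed RNG seed.
#' @return list: `agreement_noiseless` and `agreement_noisy` (2% area
#'   noise, 20% effect size).
#' @export
eval_potentiation <- function(n_spines = 100L, seed = 1L) {
  sds <- bench_seeds(seed, 2)
  agree <- function(noise_sd, effect, s) {
    tl <- simulate_timelapse(n_spines, 0.5, effect, noise_sd,
                             n_frames = 35, seed = s)
    cls <- classify_potentiated(tl)
    truth <- unique(tl[, c("spine_id", "class_true")])
    m <- merge(cls, truth, by = "spine_id")
    mean(m$class == m$class_true)
  }
  list(
    agreement_noiseless = agree(0, 0.5, sds[1]),
    agreement_noisy = agree(0.02, 0.2, sds[2])
  )
}
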