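test_that("count-distribution fit: nested RSS and trivial cases", {
  set.seed(51)
  # identical group data: F ~ 0, p ~ 1
  counts <- rep(c(1, 1, 2, 2, 2, 3, 3, 4), 2)
  grp <- rep(c("a", "b"), each = 8)
  f <- fit_count_distributions(counts, grp)
  expect_lt(f$F, 1e-6)
  expect_gt(f$p, 0.999)
  expect_gte(f$rss_shared, f$rss_separate)
  # nested-model inequality holds over random draws
  for (i in 1:20) {
    cts <- pmax(0, round(rnorm(60, 2, 1)))
    fi <- fit_count_distributions(cts, rep(c("a", "b"), 30))
    expect_gte(fi$rss_shared, fi$rss_separate - 1e-9)
  }
  # degenerate: a group with all-identical counts is flagged
  fd <- fit_count_distributions(c(rep(2, 10), c(1, 2, 2, 3, 3, 4, 1, 2, 3, 4)),
                                rep(c("a", "b"), each = 10))
  expect_true(fd$degenerate)
  expect_error(fit_count_distributions(1:10, rep("a", 10)), "2 groups")
})

test_that("count-distribution fit separates groups with distinct means", {
  set.seed(52)
  # means 1 vs 2, SD 0.5, n = 80: the curve-fit F test flags the split
  # (its histograms span only ~4 bins, so df_sep = 2 caps how extreme its
  # p can get); the exact multinomial LRT reaches p < 1e-4 essentially
  # always
  draws <- replicate(20, {
    cts <- c(pmax(0, round(rnorm(80, 1, 0.5))),
             pmax(0, round(rnorm(80, 2, 0.5))))
    g <- rep(c("a", "b"), each = 80)
    c(
      gauss = fit_count_distributions(cts, g)$p,
      multi = fit_count_distributions(cts, g, method = "multinomial")$p
    )
  })
  expect_gte(mean(draws["gauss", ] < 0.01), 0.95)
  expect_gte(mean(draws["multi", ] < 1e-4), 0.95)
})

test_that("scaling_regression matches exact lines and the OLS oracle", {
  a <- seq(0.1, 2, length.out = 20)
  f <- suppressWarnings(scaling_regression(a, 2 * a))  # exact fit
  expect_equal(f$slope, 2, tolerance = 1e-9)
  expect_equal(f$intercept, 0, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_error(scaling_regression(rep(1, 5), 1:5), "variance")
  expect_error(scaling_regression(1:2, 1:2), "n >= 3")
  # random instance against the normal-equations oracle
  set.seed(53)
  x <- runif(40, 0.1, 2); y <- 2.3 * x + rnorm(40, 0, 0.8)
  f2 <- scaling_regression(x, y)
  bo <- ols_oracle(cbind(x), y)
  expect_equal(f2$intercept, bo[1], tolerance = 1e-8)
  expect_equal(f2$slope, bo[2], tolerance = 1e-8)
  # shuffled pairing destroys the association
  ps <- replicate(40, scaling_regression(x, sample(y))$p)
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("ancova_slopes flags slope differences and not identical data", {
  set.seed(54)
  x <- runif(60, 0.1, 2)
  y <- 2.3 * x + rnorm(60, 0, 0.3)
  # identical data in both groups: p ~ 1
  f <- ancova_slopes(c(x, x), c(y, y), rep(c("a", "b"), each = 60))
  expect_gt(f$p, 0.999)
  expect_equal(unname(f$slopes[1]), unname(f$slopes[2]))
  # clearly different slopes
  y2 <- 0.5 * x + rnorm(60, 0, 0.3)
  f2 <- ancova_slopes(c(x, x), c(y, y2), rep(c("a", "b"), each = 60))
  expect_lt(f2$p, 1e-6)
  expect_error(ancova_slopes(c(x, rep(1, 60)), c(y, y2),
                             rep(c("a", "b"), each = 60)), "variance")
})

test_that("ks_compare equals the exhaustive ECDF-gap oracle", {
  expect_error(ks_compare(1, 1:5), "empty")
  a <- rnorm(100); b <- rnorm(100, 0.5)
  k <- ks_compare(a, b)
  expect_equal(k$D, ecdf_gap_oracle(a, b), tolerance = 1e-12)
  # identical samples: D = 0; disjoint supports: D = 1
  x <- seq(0.01, 1, by = 0.01)
  expect_equal(suppressWarnings(ks_compare(x, x))$D, 0)
  expect_equal(ks_compare(x, x + 10)$D, 1)
})

test_that("anova_tukey flags the shifted group only", {
  set.seed(55)
  g <- rep(c("a", "b", "c"), each = 30)
  v <- c(rnorm(30), rnorm(30), rnorm(30, 1))   # c shifted by d = 1
  res <- anova_tukey(v, g)
  expect_lt(res$p, 0.01)
  tk <- res$tukey
  expect_lt(tk$p_adj[tk$comparison == "c-a"], 0.05)
  expect_lt(tk$p_adj[tk$comparison == "c-b"], 0.05)
  expect_gt(tk$p_adj[tk$comparison == "b-a"], 0.05)
  # identical groups: all adjusted p ~ 1
  res0 <- anova_tukey(rep(rnorm(30), 3), g)
  expect_true(all(res0$tukey$p_adj > 0.999))
  expect_error(anova_tukey(rnorm(20), rep(c("a", "b"), 10)), "3 groups")
})

test_that("multivar_size_regression recovers exact and noisy models", {
  set.seed(56)
  nA <- sample(1:4, 40, replace = TRUE)
  nB <- sample(1:3, 40, replace = TRUE)
  # noiseless: coefficients to 1e-9
  area <- 0.4 * nA + 0.25 * nB + 0.5
  f <- suppressWarnings(multivar_size_regression(area, nA, nB))  # exact fit
  expect_equal(f$coefficients$estimate, c(0.4, 0.25), tolerance = 1e-9)
  expect_equal(f$intercept, 0.5, tolerance = 1e-9)
  expect_false(f$collinear)
  # against the normal-equations oracle with noise
  area2 <- area + rnorm(40, 0, 0.3)
  f2 <- multivar_size_regression(area2, nA, nB)
  bo <- ols_oracle(cbind(nA, nB), area2)
  expect_equal(c(f2$intercept, f2$coefficients$estimate), unname(bo),
               tolerance = 1e-8)
  # constant predictor: collinearity flag
  fc <- multivar_size_regression(area, nA, rep(2, 40))
  expect_true(fc$collinear)
  expect_error(multivar_size_regression(area[1:5], nA[1:5], nB[1:5]),
               "n >= 10")
})

test_that("potentiation classifier follows the sustained-increase rule", {
  mk <- function(areas, n_base = 3) {
    data.frame(
      spine_id = 1, frame = seq_along(areas),
      phase = c(rep("baseline", n_base),
                rep("post", length(areas) - n_base)),
      area_um2 = areas
    )
  }
  # noiseless +50% step: potentiated
  r1 <- classify_potentiated(mk(c(1, 1, 1, 1.5, 1.5, 1.5, 1.5, 1.5)))
  expect_equal(r1$class, "potentiated")
  # transient +20% for one frame then return: non-responsive
  r2 <- classify_potentiated(mk(c(1, 1, 1, 1.2, 1, 1, 1, 1)))
  expect_equal(r2$class, "non_responsive")
  # a sustained +5% (below the 10% rule): non-responsive
  r3 <- classify_potentiated(mk(c(1, 1, 1, rep(1.05, 5))))
  expect_equal(r3$class, "non_responsive")
  # missing frames: skipped with a message
  expect_message(
    out <- classify_potentiated(mk(c(1, 1, 1, 1.5), n_base = 3)),
    "skipped"
  )
  expect_null(out)
  # full agreement with generative labels on low-noise simulations
  tl <- simulate_timelapse(40, 0.5, 0.2, 0.005, n_frames = 25, seed = 57)
  cls <- classify_potentiated(tl)
  truth <- unique(tl[, c("spine_id", "class_true")])
  m <- merge(cls, truth, by = "spine_id")
  expect_equal(mean(m$class == m$class_true), 1)
})
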