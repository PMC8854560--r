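test_that("center_to_center nearest-neighbor distances are exact", {
  a <- data.frame(id = 1, x_nm = 0, y_nm = 0, z_nm = 0)
  b <- data.frame(id = 2, x_nm = 100, y_nm = 100, z_nm = 150)
  d <- center_to_center(a, b, "nearest_neighbor")
  expect_equal(d$distance_nm, sqrt(100^2 + 100^2 + 150^2))
  expect_equal(round(d$distance_nm, 3), 206.155)
  # identical sets: all distances zero
  s <- data.frame(id = 1:5, x_nm = runif(5, 0, 1e3), y_nm = runif(5, 0, 1e3),
                  z_nm = runif(5, 0, 1e3))
  expect_true(all(center_to_center(s, s, "nearest_neighbor")$distance_nm == 0))
  # empty B set: empty result
  expect_equal(nrow(center_to_center(s, s[0, ], "nearest_neighbor")), 0L)
})

test_that("nearest-neighbor distances match the quadratic-scan oracle", {
  set.seed(29)
  a <- data.frame(id = 1:50, x_nm = runif(50, 0, 5e3),
                  y_nm = runif(50, 0, 5e3), z_nm = runif(50, 0, 1e3))
  b <- data.frame(id = 1:50, x_nm = runif(50, 0, 5e3),
                  y_nm = runif(50, 0, 5e3), z_nm = runif(50, 0, 1e3))
  got <- center_to_center(a, b, "nearest_neighbor")
  expect_equal(got$distance_nm, nn_scan_oracle(a, b))
})

test_that("colocalized_only honors the distance rule", {
  a <- data.frame(id = 1:3, x_nm = c(0, 1000, 2000), y_nm = 0, z_nm = 0)
  b <- data.frame(id = 1:2, x_nm = c(180, 5000), y_nm = 0, z_nm = 0)
  d <- center_to_center(a, b, "colocalized_only", coloc_dist_nm = 250,
                        coloc_mode = "distance")
  expect_equal(nrow(d), 1L)
  expect_equal(d$distance_nm, 180)
})

test_that("fwhm_from_profile recovers the closed form", {
  x <- seq(0, 400, by = 5)
  # sigma 21.23 nm -> FWHM 50.0 nm
  p1 <- 80 * exp(-(x - 200)^2 / (2 * 21.23^2)) + 5
  f1 <- fwhm_from_profile(p1, 5)
  expect_lt(abs(f1 - 2.3548 * 21.23) / (2.3548 * 21.23), 0.01)
  # sigma 34 nm -> FWHM 80.06 nm
  p2 <- 60 * exp(-(x - 180)^2 / (2 * 34^2)) + 2
  f2 <- fwhm_from_profile(p2, 5)
  expect_lt(abs(f2 - 80.06) / 80.06, 0.01)
  # flat profile: flagged, excluded from averages
  f3 <- fwhm_from_profile(rep(7, 50), 5)
  expect_true(is.na(f3))
  expect_true(attr(f3, "flagged"))
})

test_that("peak_to_peak separates resolvable doublets and triples", {
  x <- seq(0, 600, by = 5)
  g <- function(c0, s) exp(-(x - c0)^2 / (2 * s^2))
  # planted 50 nm apart, sigma 21 nm
  prof <- 100 * g(275, 21) + 95 * g(325, 21) + 3
  sep <- peak_to_peak(prof, 2, 5)
  expect_false(attr(sep, "flagged"))
  expect_lt(abs(sep - 50), 2)
  # three peaks at 0/70/140 from 230: separations 70, 70
  prof3 <- 90 * g(230, 21) + 100 * g(300, 21) + 95 * g(370, 21) + 2
  sep3 <- peak_to_peak(prof3, 3, 5)
  expect_equal(length(sep3), 2L)
  expect_lt(max(abs(sep3 - 70)), 2)
  # single peak asked for two: flagged
  s1 <- peak_to_peak(100 * g(300, 21) + 2, 2, 5)
  expect_true(isTRUE(attr(s1, "flagged")))
})

test_that("bead-field measurements recover planted spacings", {
  psf <- list(fwhm_xy_nm = 50, fwhm_z_nm = 300)
  bf <- simulate_bead_field(50, n_pairs = 6, psf = psf, seed = 31)
  seps <- spinenano:::measure_bead_pairs(bf, 2L)
  expect_gte(length(seps), 4L)
  expect_lt(abs(mean(seps) - 50), 2)
  dual <- simulate_bead_field(70, n_pairs = 6, psf = psf, seed = 32,
                              dual_color = TRUE)
  seps3 <- spinenano:::measure_bead_pairs(dual, 3L)
  expect_lt(abs(mean(seps3) - 70), 2)
})

test_that("chromatic_offsets recovers null and planted shifts", {
  # zero planted shift: offsets near zero
  z0 <- spinenano:::chromatic_shift_check(0, list(fwhm_xy_nm = 50), seed = 7)
  expect_lt(z0, 5)
  # planted 30 nm lateral shift: recovered within 5 nm
  z30 <- spinenano:::chromatic_shift_check(30, list(fwhm_xy_nm = 50), seed = 8)
  expect_lt(abs(z30 - 30), 5)
  # empty punctum list: empty result
  sc <- small_scene(seed = 2, n_spines = 2L)
  res <- chromatic_offsets(sc$stack, data.frame(x_nm = numeric(0),
                                                y_nm = numeric(0)))
  expect_equal(nrow(res$per_punctum), 0L)
})
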