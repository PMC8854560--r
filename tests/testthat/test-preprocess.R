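test_that("gaussian_blur: identity at sigma 0, DC preservation, mass conservation", {
  m <- matrix(runif(64 * 64, 0, 1000), 64, 64)
  expect_identical(gaussian_blur(m, 0), m)
  expect_error(gaussian_blur(m, -1), "sigma")

  cm <- matrix(7, 32, 32)
  expect_equal(gaussian_blur(cm, 3), cm, tolerance = 1e-12)

  # central impulse: blurred mass conserved (kernel sums to 1, interior)
  im <- matrix(0, 51, 51)
  im[26, 26] <- 1
  b <- gaussian_blur(im, 2)
  expect_equal(sum(b), 1, tolerance = 1e-6)
  # and it is the separable discrete Gaussian: compare to the direct kernel
  k <- exp(-((-6:6)^2) / (2 * 2^2)); k <- k / sum(k)
  expect_equal(b[20:32, 20:32], outer(k, k), tolerance = 1e-12)
})

test_that("richardson_lucy honors its contract", {
  psf <- make_psf(100, 300, c(25, 25, 150))
  expect_equal(sum(psf), 1, tolerance = 1e-9)
  expect_true(all(psf > 0))

  v <- array(runif(32 * 32 * 7, 10, 100), c(32, 32, 7))
  expect_identical(richardson_lucy(v, psf, max_iter = 0L), v)
  expect_error(richardson_lucy(array(1, c(4, 4, 1)), psf), "larger")
  expect_error(richardson_lucy(v, psf * 2), "normalized")

  # noiseless blurred point: RL sharpens (FWHM strictly decreases) and
  # stays non-negative while approximately conserving flux
  sp <- array(0, c(41, 41, 7))
  sp <- spinenano:::stamp_spots(sp, cbind(20.5 * 25, 20.5 * 25, 3.5 * 150),
                    1000, 120, 300, c(25, 25, 150))
  dec <- richardson_lucy(sp + 1e-3, psf, max_iter = 20L)
  expect_true(all(dec >= 0))
  expect_equal(sum(dec), sum(sp + 1e-3), tolerance = 0.01 * sum(sp))
  # width as the second moment of the central profile (finer than a
  # half-max pixel count)
  fw <- function(a) {
    pr <- a[21, , 4]
    w <- pr / sum(pr)
    x <- seq_along(pr)
    sqrt(sum(w * (x - sum(w * x))^2))
  }
  expect_lt(fw(dec), fw(sp))
})

test_that("deconvolution does not shift measured inter-object distances", {
  # paired scene: distances measured with and without RL agree within 10 nm
  pf <- simulate_pair_field(16, seed = 21, n_sections = 7L)
  st <- pf$stack
  meas <- function(stack) {
    ps <- segment_seeded(stack, "PSD95")
    rc <- segment_seeded(stack, "GluA2")
    mean(center_to_center(rc, ps, "colocalized_only")$distance_nm)
  }
  d0 <- meas(st)
  st_rl <- st
  for (ch in c("PSD95", "GluA2")) {
    i <- match(ch, st$channel_labels)
    psf <- make_psf(if (ch == "PSD95") 80 else 50, 300, st$voxel_size_nm)
    st_rl$voxels[, , , i] <- pmin(
      richardson_lucy(st$voxels[, , , i, drop = TRUE], psf, 10L), 65535
    )
  }
  d1 <- meas(st_rl)
  expect_lt(abs(d1 - d0), 10)
})
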