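test_that("local_threshold follows the mean + k SD contract", {
  expect_error(local_threshold(matrix(0, 8, 8), window_px = 2), "window_px")
  # constant plane: strict inequality keeps everything background
  expect_false(any(local_threshold(matrix(5, 60, 60), 50, 2)))
  # one bright pixel on zero background: local stats of the 2500-px window
  # are mean 0.4, SD sqrt(400 - 0.16), so 1000 clears mean + 2 SD
  p <- matrix(0, 60, 60)
  p[30, 30] <- 1000
  b <- local_threshold(p, 50, 2)
  expect_true(b[30, 30])
  expect_equal(sum(b), 1L)
  # k -> large: empty foreground
  n <- matrix(runif(3600), 60, 60)
  expect_false(any(local_threshold(n, 50, 1e6)))
  # window larger than plane falls back to global stats with a warning
  expect_warning(local_threshold(matrix(rnorm(64), 8, 8), 50, 2), "global")
})

test_that("foreground shrinks monotonically in k", {
  set.seed(31)
  n <- matrix(rnorm(120 * 120, 100, 10), 120, 120)
  fg <- vapply(c(1, 1.5, 2, 3), function(k) sum(local_threshold(n, 50, k)),
               numeric(1))
  expect_true(all(diff(fg) <= 0))
})

test_that("connected_clusters applies the pixel-count and area filters", {
  vs <- c(25, 25, 150)
  # a 12-pixel blob in one section: one cluster, pixel_count 12
  b <- array(FALSE, c(40, 40, 1))
  b[10:13, 10:12, 1] <- TRUE
  cl <- connected_clusters(b, array(100, dim(b)), vs)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$max_section_px, 12L)
  expect_equal(cl$n_vox, 12L)
  # a 5-pixel blob is rejected (below the 10-pixel minimum)
  b5 <- array(FALSE, c(40, 40, 1))
  b5[cbind(c(20, 20, 20, 21, 21), c(20, 21, 22, 20, 21), 1)] <- TRUE
  expect_equal(nrow(connected_clusters(b5, array(100, dim(b5)), vs)), 0L)
  # an oversized blob is rejected (above 100 px / 0.15 um^2)
  big <- array(FALSE, c(40, 40, 1))
  big[5:25, 5:25, 1] <- TRUE
  expect_equal(nrow(connected_clusters(big, array(100, dim(big)), vs)), 0L)
})

test_that("labelling equals the brute-force flood-fill oracle", {
  set.seed(17)
  for (rep in 1:10) {
    b <- array(runif(64 * 64 * 5) < 0.12, c(64, 64, 5))
    lab <- spinenano:::label_components_3d(b)
    ora <- flood_fill_oracle(b)
    # identical partitions and identical first-voxel numbering
    expect_identical(lab, ora)
  }
})

test_that("split_touching separates resolvable doublets and leaves others", {
  vs <- c(25, 25, 150)
  mkspot <- function(centers, sigma_nm = 100) {
    v <- array(0, c(64, 64, 3))
    spinenano:::stamp_spots(
      v, cbind(centers[, 1], centers[, 2], 1.5 * 150),
      30000, sigma_nm, 100, vs
    )
  }
  detect_merged <- function(v) {
    # permissive base threshold so the doublet comes out merged
    bin <- v > 3000
    connected_clusters(bin, v, vs, max_px = 1000L, max_area_um2 = 10)
  }
  # two peaks 400 nm apart: the valley (~0.27 peak) falls below the local
  # mean + 1.5 SD separation threshold -> split into 2
  v2 <- mkspot(rbind(c(600, 800), c(1000, 800)))
  cl <- detect_merged(v2)
  expect_equal(nrow(cl), 1L)
  sp <- split_touching(v2, cl, vs)
  expect_equal(nrow(sp), 2L)
  # voxel partition: no voxel in two clusters
  keys <- unlist(lapply(sp$voxels, function(m) paste(m[, 1], m[, 2], m[, 3])))
  expect_false(any(duplicated(keys)))
  # two peaks 40 nm apart (below resolution): single maximum, unchanged
  v1 <- mkspot(rbind(c(790, 800), c(830, 800)))
  cl1 <- detect_merged(v1)
  expect_equal(nrow(split_touching(v1, cl1, vs)), nrow(cl1))
  # single Gaussian: unchanged
  v0 <- mkspot(rbind(c(800, 800)))
  cl0 <- detect_merged(v0)
  expect_equal(nrow(split_touching(v0, cl0, vs)), nrow(cl0))
})

test_that("high-SNR scene detection matches planted counts per spine", {
  sc <- small_scene(seed = 13, n_spines = 4L)
  cl <- detect_clusters(sc$stack, "PSD95")
  rois <- roi_from_truth(sc$truth, sc$stack)
  a <- assign_to_spines(cl, rois, "fully_within")
  tr <- sc$truth$clusters[sc$truth$clusters$channel == "PSD95", ]
  planted <- table(factor(tr$spine_id, levels = rois$info$id))
  detected <- table(factor(a$spine_id, levels = rois$info$id))
  expect_equal(as.numeric(detected), as.numeric(planted))
})
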