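test_that("find_maxima_3d handles ramps, doublets and plateaus", {
  # strictly decreasing ramp: single seed at the maximum corner
  r <- array(0, c(10, 10, 3))
  for (z in 1:3) r[, , z] <- outer(10:1, 10:1) + z
  mx <- find_maxima_3d(r, 3, 2)
  expect_equal(nrow(mx), 1L)
  expect_equal(unlist(mx[1, 1:3]), c(y = 1L, x = 1L, z = 3L))
  # two impulses 10 px apart (> 2 r_xy): 2 seeds
  v <- array(0, c(20, 20, 3))
  v[10, 5, 2] <- 100; v[10, 15, 2] <- 80
  expect_equal(nrow(find_maxima_3d(v, 3, 2)), 2L)
  # plateau of two equal adjacent maxima: exactly one survives, the
  # lexicographically smaller one
  p <- array(0, c(9, 9, 3))
  p[5, 4, 2] <- 50; p[5, 5, 2] <- 50
  mx <- find_maxima_3d(p, 3, 2)
  expect_equal(nrow(mx), 1L)
  expect_equal(mx$x, 4L)
  # noise floor excludes weak maxima
  expect_equal(nrow(find_maxima_3d(v, 3, 2, noise = 90)), 1L)
})

test_that("find_maxima_3d equals the exhaustive neighborhood-scan oracle", {
  set.seed(23)
  for (rep in 1:6) {
    v <- array(runif(32 * 32 * 7, 0, 1000), c(32, 32, 7))
    got <- find_maxima_3d(v, 3, 2)
    ora <- maxima_scan_oracle(v, 3, 2)
    expect_equal(got$y, ora$y)
    expect_equal(got$x, ora$x)
    expect_equal(got$z, ora$z)
  }
})

test_that("grow_objects enforces thresholds, radius clip and voxel bounds", {
  vs <- c(25, 25, 150)
  mkspot <- function(peak) {
    v <- array(0, c(33, 33, 5))
    spinenano:::stamp_spots(v, cbind(17 * 25 - 12.5, 17 * 25 - 12.5, 2.5 * 150),
                            peak, 50, 130, vs)
  }
  expect_error(
    grow_objects(mkspot(30000), data.frame(y = 17, x = 17, z = 3,
                                           value = 30000),
                 vs, local_thresh = -5),
    "local_thresh"
  )
  # peak 30000, base threshold 15000: one object holding exactly the
  # voxels at/above its object threshold within the XY radius clip
  v <- mkspot(30000)
  seeds <- find_maxima_3d(v, 3, 2)
  ob <- grow_objects(v, seeds, vs, local_thresh = 15000)
  expect_equal(nrow(ob), 1L)
  thr <- max(15000, 30000 * exp(-1.5^2 / 2))
  d <- dim(v)
  qual <- which(v >= thr)
  yy <- (qual - 1) %% d[1] + 1
  xx <- ((qual - 1) %/% d[1]) %% d[2] + 1
  qual <- qual[(yy - seeds$y[1])^2 + (xx - seeds$x[1])^2 <= 64]
  expect_equal(ob$n_vox, length(qual))
  # peak below the base threshold: no object
  expect_equal(nrow(segment_seeded(
    image_stack(array(mkspot(8000), c(33, 33, 5, 1)), vs, "a"), "a"
  )), 0L)
  # an object smaller than min_vox is discarded
  tiny <- array(0, c(15, 15, 3))
  tiny[8, 8, 2] <- 30000; tiny[8, 9, 2] <- 20000
  s2 <- find_maxima_3d(tiny, 3, 2)
  expect_equal(nrow(grow_objects(tiny, s2, vs, local_thresh = 15000)), 0L)
})

test_that("objects are disjoint, contain their seeds, and split contested voxels", {
  vs <- c(25, 25, 150)
  v <- array(0, c(40, 60, 5))
  v <- spinenano:::stamp_spots(
    v, rbind(c(20 * 25, 20 * 25, 2.5 * 150), c(30 * 25, 20 * 25, 2.5 * 150)),
    c(32000, 28000), 60, 130, vs
  )
  seeds <- find_maxima_3d(v, 3, 2, noise = 14999)
  expect_equal(nrow(seeds), 2L)
  ob <- grow_objects(v, seeds, vs)
  expect_equal(nrow(ob), 2L)
  keys <- unlist(lapply(ob$voxels, function(m) paste(m[, 1], m[, 2], m[, 3])))
  expect_false(any(duplicated(keys)))
  for (i in 1:2) {
    expect_true(paste(ob$seed_y[i], ob$seed_x[i], ob$seed_z[i]) %in%
                  paste(ob$voxels[[i]][, 1], ob$voxels[[i]][, 2],
                        ob$voxels[[i]][, 3]))
  }
})

test_that("noiseless spot centroids are within a quarter voxel of truth", {
  vs <- c(25, 25, 150)
  set.seed(41)
  for (rep in 1:5) {
    cx <- runif(1, 350, 450); cy <- runif(1, 350, 450)
    cz <- runif(1, 330, 420)
    v <- array(0, c(33, 33, 5))
    v <- spinenano:::stamp_spots(v, cbind(cx, cy, cz), 30000, 50, 130, vs)
    ob <- grow_objects(v, find_maxima_3d(v, 3, 2), vs)
    expect_equal(nrow(ob), 1L)
    expect_lt(abs(ob$x_nm - cx) / 25, 0.25)
    expect_lt(abs(ob$y_nm - cy) / 25, 0.25)
    expect_lt(abs(ob$z_nm - cz) / 150, 0.25)
  }
})

test_that("seeded and threshold paths agree on per-spine counts", {
  sc <- small_scene(seed = 14, n_spines = 4L)
  rois <- roi_from_truth(sc$truth, sc$stack)
  a1 <- assign_to_spines(detect_clusters(sc$stack, "PSD95"), rois,
                         "fully_within")
  a2 <- assign_to_spines(segment_seeded(sc$stack, "PSD95"), rois,
                         "fully_within")
  c1 <- table(factor(a1$spine_id, levels = rois$info$id))
  c2 <- table(factor(a2$spine_id, levels = rois$info$id))
  expect_gte(mean(as.numeric(c1) == as.numeric(c2)), 0.9)
})
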