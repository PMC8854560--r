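test_that("empty scene is pure background noise with empty ground truth", {
  spec <- scene_spec(field_size_px = c(64L, 64L), n_sections = 3L,
                     n_spines = 0L, seed = 2)
  sc <- generate_scene(spec)
  expect_equal(nrow(sc$truth$spines), 0L)
  expect_equal(nrow(sc$truth$clusters), 0L)
  expect_equal(nrow(sc$truth$pairs), 0L)
  # nothing but noise around the background level in every channel
  for (ch in sc$stack$channel_labels) {
    v <- get_channel(sc$stack, ch)
    expect_lt(abs(mean(v) - 400), 30)
    expect_lt(max(v), 2000)
  }
})

test_that("equal spec (incl. seed) gives voxel-identical scenes", {
  spec <- scene_spec(field_size_px = c(128L, 128L), n_sections = 5L,
                     n_spines = 2L, seed = 11)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$clusters, b$truth$clusters)
  c2 <- generate_scene(scene_spec(field_size_px = c(128L, 128L),
                                  n_sections = 5L, n_spines = 2L, seed = 12))
  expect_false(identical(a$stack$voxels, c2$stack$voxels))
})

test_that("stored pair distances equal Euclidean recomputation from centroids", {
  sc <- small_scene(seed = 5)
  tr <- sc$truth
  for (i in seq_len(nrow(tr$pairs))) {
    a <- tr$clusters[tr$clusters$id == tr$pairs$id_a[i], ]
    b <- tr$clusters[tr$clusters$id == tr$pairs$id_b[i], ]
    d <- sqrt((a$x_nm - b$x_nm)^2 + (a$y_nm - b$y_nm)^2 +
                (a$z_nm - b$z_nm)^2)
    expect_equal(tr$pairs$distance_nm[i], d, tolerance = 1e-9)
  }
})

test_that("every synaptic planted cluster has a parent spine", {
  sc <- small_scene(seed = 8)
  syn <- sc$truth$clusters[sc$truth$clusters$synaptic, ]
  expect_true(all(syn$spine_id %in% sc$truth$spines$id))
})

test_that("an over-packed field raises a sizing error", {
  expect_error(
    generate_scene(scene_spec(field_size_px = c(64L, 64L), n_sections = 3L,
                              n_spines = 20L, seed = 1)),
    "field too small"
  )
})

test_that("noiseless rendered spots have centroids within 0.25 voxel of truth", {
  # isolated spots (one per channel per grid cell) so the windowed centroid
  # sees a single cluster
  pf <- simulate_pair_field(9, seed = 4, grid_px = 40L,
                            noise_model = list(poisson = FALSE, gain = 1,
                                               read_sd_au = 0),
                            background_au = 0)
  st <- pf$stack
  dx <- st$voxel_size_nm[1]; dz <- st$voxel_size_nm[3]
  tr <- pf$truth$clusters
  for (ch in c("PSD95", "GluA2")) {
    v <- get_channel(st, ch)
    cl <- tr[tr$channel == ch, ]
    for (i in seq_len(nrow(cl))) {
      # direct intensity-weighted centroid over a window around the spot,
      # background removed
      cx <- cl$x_nm[i] / dx + 0.5
      cy <- cl$y_nm[i] / dx + 0.5
      cz <- cl$z_nm[i] / dz + 0.5
      xs <- max(1, round(cx) - 8):min(dim(v)[2], round(cx) + 8)
      ys <- max(1, round(cy) - 8):min(dim(v)[1], round(cy) + 8)
      zs <- max(1, round(cz) - 2):min(dim(v)[3], round(cz) + 2)
      w <- pmax(v[ys, xs, zs, drop = FALSE], 0)
      wx <- apply(w, 2, sum); wy <- apply(w, 1, sum); wz <- apply(w, 3, sum)
      expect_lt(abs(sum(xs * wx) / sum(wx) - cx), 0.25)
      expect_lt(abs(sum(ys * wy) / sum(wy) - cy), 0.25)
      expect_lt(abs(sum(zs * wz) / sum(wz) - cz), 0.25)
    }
  }
})

test_that("planted module count scales with head area at the configured slope", {
  # pool planted counts over many spines; least-squares slope recovers
  # modules_per_um2 within 10%
  areas <- counts <- numeric(0)
  for (s in 1:34) {
    spec <- scene_spec(field_size_px = c(320L, 320L), n_sections = 5L,
                       n_spines = 6L, seed = 100 + s,
                       noise_model = list(poisson = FALSE, gain = 1,
                                          read_sd_au = 0))
    sc <- generate_scene(spec)
    tr <- sc$truth
    psd <- tr$clusters[tr$clusters$channel == "PSD95", ]
    cnt <- table(factor(psd$spine_id, levels = tr$spines$id))
    areas <- c(areas, tr$spines$area_um2)
    counts <- c(counts, as.numeric(cnt))
  }
  expect_gte(length(areas), 200)
  slope <- unname(coef(lm(counts ~ areas))[2])
  expect_lt(abs(slope - 2.3) / 2.3, 0.10)
})

test_that("bead fields store exact spacings and reject bad geometry", {
  bf <- simulate_bead_field(50, n_pairs = 10, seed = 1)
  expect_equal(nrow(bf$truth$emitters), 20L)
  expect_true(all(bf$truth$pairs$distance_nm == 50))
  # planted positions really are 50 nm apart
  for (p in unique(bf$truth$emitters$pair)) {
    e <- bf$truth$emitters[bf$truth$emitters$pair == p, ]
    expect_equal(sqrt(diff(e$x_nm)^2 + diff(e$y_nm)^2), 50, tolerance = 1e-9)
  }
  dual <- simulate_bead_field(70, n_pairs = 4, seed = 2, dual_color = TRUE)
  e <- dual$truth$emitters[dual$truth$emitters$pair == 1, ]
  expect_identical(e$channel, c("A647", "A594", "A647"))
  steps <- sqrt(diff(e$x_nm)^2 + diff(e$y_nm)^2)
  expect_equal(steps, c(70, 70), tolerance = 1e-9)
  expect_error(simulate_bead_field(0), "spacing")
})

test_that("time-lapse generator honors its contract", {
  expect_error(simulate_timelapse(5, 0.5, 0.2, 0, n_frames = 1), "n_frames")
  # noiseless full potentiation: all post frames at +50%
  tl <- simulate_timelapse(6, 1, 0.5, 0, n_frames = 20, seed = 3)
  for (d in split(tl, tl$spine_id)) {
    base <- mean(d$area_um2[d$phase == "baseline"])
    expect_true(all(abs(d$area_um2[d$phase == "post"] / base - 1.5) < 1e-9))
  }
  # no potentiation: post frames match baseline
  tl0 <- simulate_timelapse(6, 0, 0.5, 0, n_frames = 20, seed = 3)
  for (d in split(tl0, tl0$spine_id)) {
    expect_lt(max(abs(d$area_um2 / mean(d$area_um2) - 1)), 1e-9)
  }
  expect_true(all(tl$class_true == "potentiated"))
  expect_true(all(tl0$class_true == "non_responsive"))
})

test_that("pair fields plant exact lateral offsets", {
  pf <- simulate_pair_field(25, seed = 6,
                            noise_model = list(poisson = FALSE, gain = 1,
                                               read_sd_au = 0))
  expect_equal(nrow(pf$truth$pairs), 25L)
  expect_true(all(pf$truth$pairs$distance_nm >= 150 &
                    pf$truth$pairs$distance_nm <= 200))
  # distance equals planted offset recomputed from stored centers
  cl <- pf$truth$clusters
  for (i in seq_len(nrow(pf$truth$pairs))) {
    a <- cl[cl$id == pf$truth$pairs$id_a[i], ]
    b <- cl[cl$id == pf$truth$pairs$id_b[i], ]
    expect_equal(
      sqrt((a$x_nm - b$x_nm)^2 + (a$y_nm - b$y_nm)^2 + (a$z_nm - b$z_nm)^2),
      pf$truth$pairs$distance_nm[i], tolerance = 1e-9
    )
  }
})
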