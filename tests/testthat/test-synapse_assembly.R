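# helper: minimal cluster row from a voxel index matrix
mk_cluster <- function(id, vox, channel = "X", vs = c(25, 25, 150)) {
  spinenano:::cluster_row(id, channel, vox, rep(100, nrow(vox)), vs,
                          (vs[1] / 1000)^2)
}

# helper: ROI volume with one square spine ROI spanning all sections
mk_rois <- function(d = c(40, 40, 3), y = 10:25, x = 10:25) {
  lab <- array(0L, d)
  lab[y, x, ] <- 1L
  structure(
    list(labels = lab,
         info = data.frame(id = 1L, head_area_um2 = 0.1, x_nm = 400,
                           y_nm = 400, z_nm = 225, border = FALSE,
                           compactness = 1),
         px_area_um2 = 0.000625),
    class = "spine_rois"
  )
}

test_that("assignment rules: fully_within vs partial_overlap, per section", {
  rois <- mk_rois()
  inside <- mk_cluster(1, cbind(y = 12:15, x = 12, z = 1))
  straddle <- mk_cluster(2, cbind(y = 8:12, x = 12, z = 1))
  outside <- mk_cluster(3, cbind(y = 30:33, x = 30, z = 2))
  cl <- rbind(inside, straddle, outside)
  fw <- assign_to_spines(cl, rois, "fully_within")
  expect_equal(fw$spine_id, c(1L, NA_integer_, NA_integer_))
  po <- assign_to_spines(cl, rois, "partial_overlap")
  expect_equal(po$spine_id, c(1L, 1L, NA_integer_))
  expect_error(assign_to_spines(cl, rois, "nope"), "unknown rule")
  # the rule must hold in EVERY occupied section: a cluster fully inside
  # at z=1 but entirely outside at z=2 fails both rules, while one that
  # keeps at least partial overlap per section passes partial_overlap only
  zmix <- mk_cluster(4, rbind(cbind(y = 12:14, x = 12, z = 1),
                              cbind(y = 8:9, x = 12, z = 2)))
  expect_true(is.na(assign_to_spines(zmix, rois, "fully_within")$spine_id))
  expect_true(is.na(assign_to_spines(zmix, rois, "partial_overlap")$spine_id))
  zok <- mk_cluster(5, rbind(cbind(y = 12:14, x = 12, z = 1),
                             cbind(y = 8:12, x = 12, z = 2)))
  expect_true(is.na(assign_to_spines(zok, rois, "fully_within")$spine_id))
  expect_equal(assign_to_spines(zok, rois, "partial_overlap")$spine_id, 1L)
})

test_that("pair_synapses returns mutual nearest neighbors under the cutoff", {
  post <- data.frame(id = 1, x_nm = 0, y_nm = 0, z_nm = 0)
  pre <- data.frame(id = 10, x_nm = 300, y_nm = 0, z_nm = 0)
  p <- pair_synapses(post, pre)
  expect_equal(nrow(p), 1L)
  expect_equal(p$distance_nm, 300)
  # beyond the cutoff: no pair
  pre_far <- data.frame(id = 10, x_nm = 900, y_nm = 0, z_nm = 0)
  expect_equal(nrow(pair_synapses(post, pre_far)), 0L)
  # 2 post vs 1 pre: exactly one (mutual) pair — exhaustively checked
  post2 <- data.frame(id = 1:2, x_nm = c(0, 400), y_nm = 0, z_nm = 0)
  pre1 <- data.frame(id = 10, x_nm = 150, y_nm = 0, z_nm = 0)
  p2 <- pair_synapses(post2, pre1)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$post_id, 1L)  # 150 < 250: post 1 is the mutual NN
  expect_equal(p2$distance_nm, 150)
})

test_that("receptor classification requires a juxtaposed scaffold partner", {
  vs <- c(25, 25, 150)
  scaffold <- rbind(
    mk_cluster(1, cbind(y = 10:12, x = 10, z = 1)),     # juxtaposed
    mk_cluster(2, cbind(y = 30:32, x = 30, z = 1))      # not juxtaposed
  )
  pairs <- data.frame(post_id = 1L, pre_id = 99L, distance_nm = 300)
  rec <- rbind(
    mk_cluster(11, cbind(y = 11:12, x = 10:11, z = 1)), # overlaps scaffold 1
    mk_cluster(12, cbind(y = 31:32, x = 30, z = 1)),    # overlaps scaffold 2
    mk_cluster(13, cbind(y = 38:39, x = 2, z = 2))      # isolated
  )
  out <- classify_receptor_clusters(rec, scaffold, pairs)
  expect_equal(out$synaptic, c(TRUE, FALSE, FALSE))
  expect_equal(out$partner_id, c(1L, NA_integer_, NA_integer_))
})

test_that("per-spine records conserve counts and feed summaries", {
  sc <- small_scene(seed = 15, n_spines = 4L)
  rois <- roi_from_truth(sc$truth, sc$stack)
  cfg <- default_config()
  res <- analyze_stack(sc$stack, cfg, rois = rois)
  rec <- res$records
  # conservation: synaptic + non-synaptic equals all assigned receptors
  glua2 <- res$clusters$GluA2
  assigned <- sum(!is.na(glua2$spine_id))
  expect_equal(sum(rec$n_GluA2) + sum(rec$n_GluA2_nonsyn), assigned)
  # every synaptic receptor has a partner in the pair list
  syn <- glua2[glua2$synaptic, ]
  expect_true(all(syn$partner_id %in% res$pairs$post_id))
  sm <- res$summaries
  expect_true(all(sm$occupancy_pct$pct >= 0 & sm$occupancy_pct$pct <= 100))
  # count-distribution percentages sum to 100 per channel (spines with >0)
  for (ch in unique(sm$count_distribution_pct$channel)) {
    s <- sum(sm$count_distribution_pct$pct[
      sm$count_distribution_pct$channel == ch])
    if (s > 0) expect_equal(s, 100, tolerance = 1e-9)
  }
})

test_that("summaries handle trivial inputs", {
  empty <- summarize_spines(data.frame())
  expect_equal(nrow(empty$occupancy_pct), 0L)
  rec <- data.frame(spine_id = 1:10, head_area_um2 = 0.5,
                    n_GluA2 = 1L, n_GluA2_nonsyn = 0L)
  sm <- summarize_spines(rec)
  expect_equal(sm$occupancy_pct$pct, 100)
  expect_equal(sm$count_distribution_pct$pct[
    sm$count_distribution_pct$count == "1"], 100)
  expect_equal(sm$synaptic_only_pct$only_synaptic_pct, 100)
  # spine with synaptic and non-synaptic clusters lands in "both"
  rec2 <- data.frame(spine_id = 1:2, head_area_um2 = 0.5,
                     n_GluA2 = c(2L, 1L), n_GluA2_nonsyn = c(1L, 0L))
  sm2 <- summarize_spines(rec2)
  expect_equal(sm2$synaptic_only_pct$both_pct, 50)
})
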