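#' Default pipeline configuration
#'
#' Every analysis parameter surfaced with its standard default: spine
#' masking (2 px blur, mean + 2 SD global threshold), nanocluster
#' detection (50 px local window, mean + 2 SD, 10--100 px and
#' 0.002--0.15 um^2 size filters, mean + 1.5 SD separation rule), seeded
#' segmentation (maxima radii 3 px XY / 2 sections z, base threshold
#' 15000 AU in the 10000--20000 working range, 8 px max radius, SD
#' multiplier 1.5, 3--20000 voxel bounds), assembly (500 nm juxtaposition,
#' 250 nm colocalization fallback) and preprocessing (deconvolution off by
#' default, 40 iterations when on).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    channels = list(
      fill = "GFP",
      post_scaffold = "PSD95",
      pre_scaffold = "Bassoon",
      receptors = list("GluA2")
    ),
    preprocess = list(
      blur_sigma_px = 2,
      deconvolve = FALSE,
      rl_iters = 40
    ),
    spine = list(
      k_sd = 2,
      blur_sigma_px = 2,
      min_area_um2 = 0.05,
      max_area_um2 = 3,
      compactness_min = 0.5
    ),
    detect = list(
      window_px = 50,
      k = 2,
      k_sep = 1.5,
      min_px = 10,
      max_px = 100,
      min_area_um2 = 0.002,
      max_area_um2 = 0.15
    ),
    segment = list(
      r_xy = 3,
      r_z = 2,
      noise = 0,
      local_thresh = 15000,
      max_radius_px = 8,
      sd_gauss = 1.5,
      min_vox = 3,
      max_vox = 20000
    ),
    assembly = list(
      juxtaposition_max_nm = 500,
      coloc_max_nm = 250,
      coloc_mode = "either"
    ),
    distance = list(
      mode = "colocalized_only",
      max_pair_nm = 500
    ),
    segmenter = "threshold",
    scene = list(seed = 1)
  )
}

#' Load a YAML config merged over the defaults
#'
#' @param path YAML file (optional; `NULL` returns the defaults).
#' @return nested named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Run the full analysis on one stack
#'
#' Stages in order: optional per-channel Richardson-Lucy deconvolution;
#' spine masking from the fill channel (or truth-seeded ROIs);
#' nanocluster segmentation per STED channel (threshold path or seeded
#' path per `config$segmenter`); cluster-to-spine assignment
#' (postsynaptic channels fully-within, presynaptic partial-overlap);
#' juxtaposition pairing; receptor synaptic/non-synaptic classification;
#' per-spine records and summaries; center-to-center distance tables.
#'
#' @param stack an [image_stack].
#' @param config configuration list ([default_config()] shape).
#' @param rois optional precomputed `spine_rois` (e.g. [roi_from_truth()]).
#' @return list: `rois` info, `clusters` (named per channel), `pairs`,
#'   `records`, `summaries`, `distances`.
#' @export
analyze_stack <- function(stack, config = default_config(), rois = NULL) {
  ch <- config$channels
  rec_labs <- unlist(ch$receptors)
  sted_labs <- intersect(c(ch$post_scaffold, ch$pre_scaffold, rec_labs),
                         stack$channel_labels)
  if (isTRUE(config$preprocess$deconvolve)) {
    for (lb in sted_labs) {
      i <- match(lb, stack$channel_labels)
      psf <- make_psf(100, 300, stack$voxel_size_nm)
      stack$voxels[, , , i] <- clamp(
        richardson_lucy(stack$voxels[, , , i, drop = TRUE], psf,
                        config$preprocess$rl_iters),
        0, 65535
      )
    }
  }
  if (is.null(rois)) {
    rois <- make_spine_rois(
      stack, ch$fill,
      min_area_um2 = config$spine$min_area_um2,
      max_area_um2 = config$spine$max_area_um2,
      blur_sigma_px = config$spine$blur_sigma_px,
      k_sd = config$spine$k_sd,
      compactness_min = config$spine$compactness_min
    )
  }
  seg <- function(lb) {
    if (identical(config$segmenter, "seeded")) {
      segment_seeded(
        stack, lb,
        r_xy = config$segment$r_xy, r_z = config$segment$r_z,
        noise = config$segment$noise,
        local_thresh = config$segment$local_thresh,
        max_radius_px = config$segment$max_radius_px,
        sd_gauss = config$segment$sd_gauss,
        min_vox = config$segment$min_vox, max_vox = config$segment$max_vox
      )
    } else {
      detect_clusters(
        stack, lb,
        window_px = config$detect$window_px, k = config$detect$k,
        k_sep = config$detect$k_sep,
        min_px = config$detect$min_px, max_px = config$detect$max_px,
        min_area_um2 = config$detect$min_area_um2,
        max_area_um2 = config$detect$max_area_um2
      )
    }
  }
  clusters <- stats::setNames(lapply(sted_labs, seg), sted_labs)
  post <- clusters[[ch$post_scaffold]]
  pre <- if (ch$pre_scaffold %in% names(clusters)) {
    clusters[[ch$pre_scaffold]]
  } else {
    empty_clusters()
  }
  post <- assign_to_spines(post, rois, "fully_within")
  if (nrow(pre)) pre <- assign_to_spines(pre, rois, "partial_overlap")
  pairs <- pair_synapses(post, pre, config$assembly$juxtaposition_max_nm)
  assigned <- list()
  assigned[[ch$post_scaffold]] <- post
  if (ch$pre_scaffold %in% names(clusters)) {
    assigned[[ch$pre_scaffold]] <- pre
  }
  distances <- list()
  for (rl in intersect(rec_labs, names(clusters))) {
    rc <- assign_to_spines(clusters[[rl]], rois, "fully_within")
    rc <- classify_receptor_clusters(
      rc, post, pairs,
      coloc_mode = config$assembly$coloc_mode,
      coloc_dist_nm = config$assembly$coloc_max_nm
    )
    assigned[[rl]] <- rc
    distances[[paste(ch$post_scaffold, rl, sep = "-")]] <- center_to_center(
      rc[rc$synaptic, , drop = FALSE], post,
      mode = "colocalized_only",
      coloc_dist_nm = config$assembly$coloc_max_nm,
      coloc_mode = config$assembly$coloc_mode
    )
  }
  if (nrow(pairs)) {
    distances[[paste(ch$post_scaffold, ch$pre_scaffold, sep = "-")]] <-
      data.frame(
        id_a = pairs$post_id, id_b = pairs$pre_id,
        distance_nm = pairs$distance_nm, relation = "juxtaposed"
      )
  }
  records <- spine_records(assigned, rois)
  list(
    rois = rois,
    clusters = assigned,
    pairs = pairs,
    records = records,
    summaries = summarize_spines(records),
    distances = distances
  )
}

#' Simulate a scene and write it to disk
#'
#' Writes the rendered stack (multi-plane TIFF + JSON sidecar), the
#' ground-truth cluster and spine tables (CSV, coordinates in nm) and the
#' resolved scene spec (JSON) into `out_dir`.
#'
#' @param config configuration list; `config$scene` entries override
#'   [scene_spec()] defaults.
#' @param out_dir output directory (created if missing).
#' @param seed optional seed override (takes precedence over the config).
#' @return named list of written paths.
#' @export
run_simulate <- function(config = default_config(), out_dir = ".",
                         seed = NULL) {
  sc <- config$scene
  if (!is.null(seed)) sc$seed <- seed
  spec <- do.call(scene_spec, sc)
  scene <- generate_scene(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p_tif <- file.path(out_dir, "scene.tif")
  write_stack(scene$stack, p_tif)
  p_cl <- file.path(out_dir, "truth_clusters.csv")
  write_tables(scene$truth$clusters, p_cl)
  p_sp <- file.path(out_dir, "truth_spines.csv")
  write_tables(scene$truth$spines, p_sp)
  p_pr <- file.path(out_dir, "truth_pairs.csv")
  write_tables(scene$truth$pairs, p_pr)
  p_spec <- file.path(out_dir, "scene_spec.json")
  ser <- spec
  class(ser) <- NULL
  jsonlite::write_json(ser, p_spec, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(stack = p_tif, truth_clusters = p_cl, truth_spines = p_sp,
                 truth_pairs = p_pr, spec = p_spec))
}

#' Analyze stacks on disk and write result tables
#'
#' @param config configuration list.
#' @param stack_paths TIFF paths readable by [read_stack()].
#' @param out_dir output directory.
#' @param truth_path optional ground-truth cluster CSV; when given, a
#'   recovery report comparing detected to planted per-spine counts is
#'   written as well.
#' @return named list of written paths (per stack).
#' @export
run_analyze <- function(config = default_config(), stack_paths,
                        out_dir = ".", truth_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- list()
  for (sp in stack_paths) {
    stack <- read_stack(sp)
    res <- analyze_stack(stack, config)
    base <- tools::file_path_sans_ext(basename(sp))
    p_rec <- file.path(out_dir, paste0(base, "_spine_records.csv"))
    write_tables(res$records, p_rec)
    base_cols <- c("id", "channel", "n_vox", "max_section_px", "area_um2",
                   "x_nm", "y_nm", "z_nm", "total_intensity", "spine_id")
    cl <- do.call(rbind, lapply(res$clusters, function(x) {
      keep <- intersect(base_cols, names(x))
      out <- x[, keep, drop = FALSE]
      out$synaptic <- if ("synaptic" %in% names(x)) x$synaptic else NA
      out
    }))
    p_cl <- file.path(out_dir, paste0(base, "_clusters.csv"))
    write_tables(cl, p_cl)
    dl <- do.call(rbind, lapply(names(res$distances), function(nm) {
      d <- res$distances[[nm]]
      if (!nrow(d)) return(NULL)
      d$pair <- nm
      d
    }))
    p_d <- file.path(out_dir, paste0(base, "_distances.csv"))
    write_tables(if (is.null(dl)) data.frame(
      id_a = integer(0), id_b = integer(0), distance_nm = numeric(0),
      relation = character(0), pair = character(0)
    ) else dl, p_d)
    paths <- list(records = p_rec, clusters = p_cl, distances = p_d)
    if (!is.null(truth_path)) {
      truth_cl <- read_tables(truth_path)
      rep_df <- recovery_report(res, truth_cl)
      p_rr <- file.path(out_dir, paste0(base, "_recovery.csv"))
      write_tables(rep_df, p_rr)
      paths$recovery <- p_rr
    }
    cfg_snap <- file.path(out_dir, paste0(base, "_config.json"))
    jsonlite::write_json(config, cfg_snap, auto_unbox = TRUE, digits = NA)
    paths$config <- cfg_snap
    outs[[base]] <- paths
  }
  invisible(outs)
}

# detected vs planted: join each detected cluster to the nearest planted
# cluster of the same channel
recovery_report <- function(res, truth_clusters) {
  out <- list()
  for (ch in names(res$clusters)) {
    det <- res$clusters[[ch]]
    tr <- truth_clusters[truth_clusters$channel == ch, , drop = FALSE]
    if (!nrow(det)) next
    if (!nrow(tr)) {
      out[[ch]] <- data.frame(
        channel = ch, det_id = det$id, truth_id = NA_integer_,
        match_dist_nm = NA_real_
      )
      next
    }
    dm <- sqrt(
      outer(det$x_nm, tr$x_nm, "-")^2 +
        outer(det$y_nm, tr$y_nm, "-")^2 +
        outer(det$z_nm, tr$z_nm, "-")^2
    )
    j <- apply(dm, 1, which.min)
    out[[ch]] <- data.frame(
      channel = ch, det_id = det$id, truth_id = tr$id[j],
      match_dist_nm = dm[cbind(seq_len(nrow(det)), j)]
    )
  }
  if (!length(out)) {
    return(data.frame(channel = character(0), det_id = integer(0),
                      truth_id = integer(0), match_dist_nm = numeric(0)))
  }
  do.call(rbind, out)
}

#' Run the optical calibration battery on synthetic bead fields
#'
#' Single-color bead pairs at `spacing_nm` and dual-color triples at
#' `dual_spacing_nm` are simulated and measured with [peak_to_peak()];
#' single-emitter FWHM is measured with [fwhm_from_profile()]; a planted
#' lateral chromatic shift is recovered with [chromatic_offsets()].
#'
#' @param config configuration list (unused fields ignored).
#' @param seed RNG seed.
#' @param spacing_nm single-color bead spacing (default 50).
#' @param dual_spacing_nm dual-color step (default 70).
#' @param shift_nm planted chromatic shift for the offset check
#'   (default 30).
#' @param n_pairs bead pairs per field.
#' @return data.frame of calibration measurements.
#' @export
run_calibrate <- function(config = default_config(), seed = 1L,
                          spacing_nm = 50, dual_spacing_nm = 70,
                          shift_nm = 30, n_pairs = 10L) {
  psf <- list(fwhm_xy_nm = 50, fwhm_z_nm = 300)
  bf <- simulate_bead_field(spacing_nm, n_pairs, psf, seed = seed)
  p2p <- measure_bead_pairs(bf, n_peaks = 2L)
  df <- simulate_bead_field(dual_spacing_nm, n_pairs, psf, seed = seed + 1L,
                            dual_color = TRUE)
  p2p_dual <- measure_bead_pairs(df, n_peaks = 3L)
  single <- simulate_bead_field(10 * psf$fwhm_xy_nm, 4L, psf,
                                seed = seed + 2L)
  fw <- measure_bead_fwhm(single)
  cs <- chromatic_shift_check(shift_nm, psf, seed = seed + 3L)
  data.frame(
    measure = c("peak_to_peak_nm", "dual_color_step_nm", "fwhm_nm",
                "chromatic_lateral_nm"),
    planted = c(spacing_nm, dual_spacing_nm, psf$fwhm_xy_nm, shift_nm),
    measured = c(mean(p2p), mean(p2p_dual), mean(fw), cs)
  )
}

# profile through each bead pair along its planted axis; mean separations
measure_bead_pairs <- function(bf, n_peaks) {
  px <- bf$stack$voxel_size_nm[1]
  ch <- get_channel(bf$stack, "A647")
  if (n_peaks == 3L) {
    # dual-color: sum both channels so the middle bead appears
    ch <- ch + get_channel(bf$stack, "A594")
  }
  if (is.matrix(ch)) dim(ch) <- c(dim(ch), 1L)
  em <- bf$truth$emitters
  out <- numeric(0)
  for (p in unique(em$pair)) {
    e <- em[em$pair == p, ]
    ctr <- c(mean(e$x_nm), mean(e$y_nm))
    u <- c(cos(e$angle[1]), sin(e$angle[1]))
    half <- max(dist(cbind(e$x_nm, e$y_nm))) / 2 + 150
    prof <- line_profile(ch[, , 1], ctr - half * u, ctr + half * u, px)
    sep <- peak_to_peak(prof, n_peaks, 5)
    if (!isTRUE(attr(sep, "flagged"))) out <- c(out, sep)
  }
  out
}

measure_bead_fwhm <- function(bf) {
  px <- bf$stack$voxel_size_nm[1]
  ch <- get_channel(bf$stack, "A647")
  if (is.matrix(ch)) dim(ch) <- c(dim(ch), 1L)
  em <- bf$truth$emitters
  out <- numeric(0)
  for (i in seq_len(nrow(em))) {
    p0 <- c(em$x_nm[i] - 200, em$y_nm[i])
    p1 <- c(em$x_nm[i] + 200, em$y_nm[i])
    prof <- line_profile(ch[, , 1], p0, p1, px)
    f <- fwhm_from_profile(prof, 5)
    if (!isTRUE(attr(f, "flagged"))) out <- c(out, f)
  }
  out
}

# render one triple-labeled punctum with a planted lateral shift on the
# third channel; return the recovered shift magnitude
chromatic_shift_check <- function(shift_nm, psf, seed = 1L, px_nm = 25) {
  with_seed(seed, {
    n <- 96L
    ctr <- c(n / 2 * px_nm, n / 2 * px_nm)
    ang <- stats::runif(1, 0, 2 * pi)
    sh <- shift_nm * c(cos(ang), sin(ang))
    v <- array(200, c(n, n, 5L, 3L))
    s_xy <- 80 * FWHM_TO_SIGMA
    pos <- list(ctr, ctr, ctr + sh)
    for (ci in 1:3) {
      chv <- v[, , , ci, drop = TRUE]
      chv <- stamp_spot(chv, c(pos[[ci]], 3 * 150), 20000, s_xy,
                        300 * FWHM_TO_SIGMA, c(px_nm, px_nm, 150))
      v[, , , ci] <- chv
    }
    v[] <- round(clamp(v + stats::rnorm(length(v), 0, 20), 0, 65535))
    st <- image_stack(v, c(px_nm, px_nm, 150), c("ch425", "ch594", "ch647"))
    res <- chromatic_offsets(
      st, data.frame(x_nm = ctr[1], y_nm = ctr[2]),
      channels = c("ch425", "ch647")
    )
    res$per_punctum$lateral_nm[1]
  })
}

#' Render the summary report tables from result CSVs
#'
#' @param records_csv spine-record CSV written by [run_analyze()].
#' @param distances_csv distance CSV written by [run_analyze()].
#' @param out_dir output directory.
#' @return named list of written paths.
#' @export
run_report <- function(records_csv, distances_csv = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- read_tables(records_csv)
  sm <- summarize_spines(rec)
  paths <- list()
  for (nm in names(sm)) {
    p <- file.path(out_dir, paste0("report_", nm, ".csv"))
    write_tables(sm[[nm]], p)
    paths[[nm]] <- p
  }
  if (!is.null(distances_csv)) {
    d <- read_tables(distances_csv)
    if (nrow(d)) {
      agg <- do.call(rbind, lapply(split(d, d$pair), function(x) {
        data.frame(
          pair = x$pair[1], n = nrow(x),
          mean_nm = mean(x$distance_nm),
          sem_nm = stats::sd(x$distance_nm) / sqrt(nrow(x))
        )
      }))
      rownames(agg) <- NULL
      p <- file.path(out_dir, "report_distances.csv")
      write_tables(agg, p)
      paths$distances <- p
    }
  }
  invisible(paths)
}
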