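#' Global spine-mask threshold from the cell-fill channel
#'
#' Threshold = mean + k * SD over all voxel intensities of the (blurred)
#' fill-channel field; k defaults to 2. SD is the population SD (divide by
#' N) for determinism; at whole-field scale the distinction is negligible.
#'
#' @param gfp 3-D `[y, x, z]` array of the (already blurred) fill channel.
#' @param k_sd SD multiplier (default 2).
#' @return threshold in AU.
#' @export
spine_threshold <- function(gfp, k_sd = 2) {
  if (!length(gfp)) stop("empty image")
  n <- length(gfp)
  mu <- mean(gfp)
  sd_pop <- sqrt(sum((gfp - mu)^2) / n)
  mu + k_sd * sd_pop
}

#' Build spine-head ROIs from the cell-fill channel
#'
#' blur (sigma 2 px, lateral) -> global mean + 2 SD threshold -> binary;
#' per-section 8-connected components are linked across z wherever they
#' overlap by at least one pixel. The head area of an ROI is the area of
#' its maximal-area single z-section (the best-focus outline of the head).
#' Spine-like components are selected by area bounds and a compactness
#' filter (max-section area / convex-hull area); components touching the
#' field border are flagged.
#'
#' @param gfp_stack an [image_stack] or a 3-D `[y, x, z]` array.
#' @param fill_label channel label of the cell fill (default `"GFP"`),
#'   used when a full stack is supplied.
#' @param min_area_um2,max_area_um2 head-area bounds (defaults 0.05 and 3).
#' @param blur_sigma_px pre-threshold blur sigma (default 2).
#' @param k_sd threshold SD multiplier (default 2).
#' @param compactness_min minimum area / convex-area ratio (default 0.5).
#' @param min_z_sections minimum number of sections an ROI must span
#'   (default 2 when the stack has more than one section). A confocal
#'   axial FWHM of ~600 nm makes a real spine head persist across several
#'   150 nm sections, whereas blurred-noise excursions are single-section.
#' @return A `spine_rois` object: `labels` (integer `[y, x, z]` volume,
#'   0 = background), `info` (data.frame: `id`, `head_area_um2`, centroid
#'   nm, `border`, `compactness`), `px_area_um2`.
#' @export
make_spine_rois <- function(gfp_stack, fill_label = "GFP",
                            min_area_um2 = 0.05, max_area_um2 = 3,
                            blur_sigma_px = 2, k_sd = 2,
                            compactness_min = 0.5, min_z_sections = NULL) {
  if (inherits(gfp_stack, "image_stack")) {
    vsz <- gfp_stack$voxel_size_nm
    gfp <- get_channel(gfp_stack, fill_label)
  } else {
    stop("make_spine_rois needs an image_stack (for physical calibration)")
  }
  px_area <- (vsz[1] / 1000)^2
  sm <- gaussian_blur(gfp, blur_sigma_px)
  thr <- spine_threshold(sm, k_sd)
  bin <- sm > thr
  lab <- label_components_3d(bin)
  if (max(lab) == 0L) {
    return(structure(
      list(labels = lab,
           info = data.frame(
             id = integer(0), head_area_um2 = numeric(0), x_nm = numeric(0),
             y_nm = numeric(0), z_nm = numeric(0), border = logical(0),
             compactness = numeric(0)
           ),
           px_area_um2 = px_area),
      class = "spine_rois"
    ))
  }
  vox <- label_voxels(lab)
  d <- dim(lab)
  keep <- integer(0)
  rows <- list()
  if (is.null(min_z_sections)) {
    min_z_sections <- if (dim(lab)[3] > 1L) 2L else 1L
  }
  for (nm_id in names(vox)) {
    vv <- vox[[nm_id]]
    # maximal-area single section
    per_z <- table(vv[, "z"])
    # persistence: the head must keep at least half its maximal section
    # area across min_z_sections sections (noise blobs link to adjacent
    # sections only through isolated specks)
    if (sum(per_z >= max(per_z) / 2) < min_z_sections) next
    zbest <- as.integer(names(per_z)[which.max(per_z)])
    npx <- max(per_z)
    head_area <- npx * px_area
    if (head_area < min_area_um2 || head_area > max_area_um2) next
    sec <- vv[vv[, "z"] == zbest, , drop = FALSE]
    comp <- 1
    if (nrow(sec) >= 3L) {
      h <- grDevices::chull(sec[, "x"], sec[, "y"])
      hull_area <- polygon_area(cbind(sec[h, "x"], sec[h, "y"])) +
        nrow(sec[h, , drop = FALSE]) / 2 + 1  # pick-like pixel correction
      comp <- min(1, nrow(sec) / max(hull_area, 1))
    }
    if (comp < compactness_min) next
    border <- any(vv[, "y"] == 1L | vv[, "y"] == d[1] |
                    vv[, "x"] == 1L | vv[, "x"] == d[2])
    wt <- sm[vv]
    ct <- centroid_nm(vv, wt, vsz)
    keep <- c(keep, as.integer(nm_id))
    rows[[length(rows) + 1L]] <- data.frame(
      id = as.integer(nm_id), head_area_um2 = head_area,
      x_nm = ct["x_nm"], y_nm = ct["y_nm"], z_nm = ct["z_nm"],
      border = border, compactness = comp
    )
  }
  lab[!(lab %in% keep)] <- 0L
  # renumber 1..K in ascending old-id order
  if (length(keep)) {
    ord <- sort(keep)
    lab[] <- match(lab, ord, nomatch = 0L)
    info <- do.call(rbind, rows)
    info <- info[order(info$id), , drop = FALSE]
    info$id <- seq_len(nrow(info))
    rownames(info) <- NULL
  } else {
    info <- data.frame(
      id = integer(0), head_area_um2 = numeric(0), x_nm = numeric(0),
      y_nm = numeric(0), z_nm = numeric(0), border = logical(0),
      compactness = numeric(0)
    )
  }
  structure(
    list(labels = lab, info = info, px_area_um2 = px_area),
    class = "spine_rois"
  )
}
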