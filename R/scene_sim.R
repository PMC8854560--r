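#' Specification of a synthetic STED-like scene
#'
#' Bundles every parameter of the ground-truthed scene generator. The
#' defaults emulate the imaging geometry and effect structure the package
#' is built around: 1024 x 1024 fields at 25 nm pixels, 15 sections at
#' 150 nm spacing; GFP-filled spine heads of ~0.1--2 um^2 whose planted
#' nanomodule count scales linearly with head area at ~2.3 modules/um^2;
#' STED channels with ~50 nm (775 nm depletion) or ~80 nm (592 nm
#' depletion) lateral FWHM and ~300 nm axial FWHM; receptor-to-scaffold
#' lateral offsets of 150--200 nm and pre-to-post offsets of ~300--450 nm
#' across a 100 nm axial cleft gap; Poisson photon noise plus Gaussian read
#' noise on a 16-bit scale.
#'
#' @param field_size_px `(ny, nx)` pixels per section.
#' @param n_sections number of z sections.
#' @param voxel_size_nm `(dx, dy, dz)`, `dx == dy`.
#' @param n_spines number of spine heads to plant.
#' @param spine_area_dist list `(meanlog, sdlog, min, max)` of the
#'   log-normal head-area distribution (um^2), truncated to `[min, max]`.
#' @param modules_per_um2 slope of planted module count vs head area.
#' @param min_module_sep_nm minimum center separation of modules in a head.
#' @param spine_margin_nm minimum distance of a module center from the head
#'   edge (keeps rendered clusters entirely within the head ROI).
#' @param min_spine_spacing_nm minimum center spacing between spine heads.
#' @param channel_specs data.frame with columns `label`, `role`
#'   (`fill` / `post_scaffold` / `pre_scaffold` / `receptor`),
#'   `fwhm_xy_nm`, `fwhm_z_nm`, `peak_au`, `background_au`.
#' @param offset_model data.frame with columns `channel`, `ref`,
#'   `lateral_min_nm`, `lateral_max_nm` (uniform lateral offset from the
#'   reference scaffold cluster), `axial_gap_nm`, `axial_sd_nm`.
#' @param cluster_area_dist list `(meanlog, sdlog, min, max)` for planted
#'   cluster areas (um^2), truncated to the 0.002--0.15 um^2 regime.
#' @param noise_model list `(poisson, gain, read_sd_au)`; set
#'   `poisson = FALSE` and `read_sd_au = 0` for noiseless renders.
#' @param nonsynaptic_rate expected non-synaptic receptor clusters per
#'   spine per receptor channel (Poisson).
#' @param max_modules_per_spine hard cap on planted modules per head
#'   (default 8; heads too small for a count keep the largest count their
#'   geometry allows at the separation/margin constraints).
#' @param receptor_occupancy probability that a scaffold module carries a
#'   synaptic receptor cluster.
#' @param pre_occupancy probability that a scaffold module is juxtaposed by
#'   a presynaptic cluster.
#' @param seed integer RNG seed; equal specs give bit-identical scenes.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(field_size_px = c(1024L, 1024L),
                       n_sections = 15L,
                       voxel_size_nm = c(25, 25, 150),
                       n_spines = 12L,
                       spine_area_dist = list(
                         meanlog = log(0.6), sdlog = 0.5, min = 0.1, max = 2
                       ),
                       modules_per_um2 = 2.3,
                       min_module_sep_nm = 250,
                       spine_margin_nm = 150,
                       min_spine_spacing_nm = 1500,
                       channel_specs = default_channel_specs(),
                       offset_model = default_offset_model(),
                       cluster_area_dist = list(
                         meanlog = log(0.012), sdlog = 0.5,
                         min = 0.002, max = 0.15
                       ),
                       noise_model = list(
                         poisson = TRUE, gain = 1, read_sd_au = 100
                       ),
                       nonsynaptic_rate = 1.5,
                       receptor_occupancy = 0.9,
                       pre_occupancy = 0.95,
                       max_modules_per_spine = 8L,
                       seed = 1L) {
  spec <- list(
    field_size_px = as.integer(field_size_px),
    n_sections = as.integer(n_sections),
    voxel_size_nm = as.numeric(voxel_size_nm),
    n_spines = as.integer(n_spines),
    spine_area_dist = spine_area_dist,
    modules_per_um2 = modules_per_um2,
    min_module_sep_nm = min_module_sep_nm,
    spine_margin_nm = spine_margin_nm,
    min_spine_spacing_nm = min_spine_spacing_nm,
    channel_specs = channel_specs,
    offset_model = offset_model,
    cluster_area_dist = cluster_area_dist,
    noise_model = noise_model,
    nonsynaptic_rate = nonsynaptic_rate,
    receptor_occupancy = receptor_occupancy,
    pre_occupancy = pre_occupancy,
    max_modules_per_spine = as.integer(max_modules_per_spine),
    seed = as.integer(seed)
  )
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

#' @rdname scene_spec
#' @export
default_channel_specs <- function() {
  data.frame(
    label = c("GFP", "PSD95", "Bassoon", "GluA2"),
    role = c("fill", "post_scaffold", "pre_scaffold", "receptor"),
    fwhm_xy_nm = c(250, 80, 50, 50),
    fwhm_z_nm = c(600, 300, 300, 300),
    peak_au = c(15000, 33000, 33000, 33000),
    background_au = c(400, 400, 400, 400),
    stringsAsFactors = FALSE
  )
}

#' @rdname scene_spec
#' @export
default_offset_model <- function() {
  data.frame(
    channel = c("GluA2", "Bassoon"),
    ref = c("PSD95", "PSD95"),
    lateral_min_nm = c(150, 280),
    lateral_max_nm = c(200, 440),
    axial_gap_nm = c(0, 100),
    axial_sd_nm = c(0, 0),
    stringsAsFactors = FALSE
  )
}

validate_scene_spec <- function(spec) {
  stopifnot(
    length(spec$field_size_px) == 2L, all(spec$field_size_px >= 8L),
    spec$n_sections >= 1L,
    spec$voxel_size_nm[1] == spec$voxel_size_nm[2],
    all(spec$voxel_size_nm > 0),
    spec$n_spines >= 0L,
    spec$modules_per_um2 > 0,
    all(spec$channel_specs$fwhm_xy_nm > 0),
    all(spec$channel_specs$fwhm_z_nm > 0),
    sum(spec$channel_specs$role == "fill") == 1L,
    spec$noise_model$gain > 0 || !spec$noise_model$poisson
  )
  invisible(spec)
}

FWHM_TO_SIGMA <- 1 / 2.3548

# truncated log-normal draw
rlnorm_trunc <- function(n, d) {
  clamp(stats::rlnorm(n, d$meanlog, d$sdlog), d$min, d$max)
}

# Largest module count placeable in a disk of radius rho_nm with pairwise
# separation sep_nm (regular polygon circumradius rule).
max_modules <- function(rho_nm, sep_nm, cap = 8L) {
  if (rho_nm < 0) return(0L)
  k <- 1L
  for (kk in 2:cap) {
    if (sep_nm / (2 * sin(pi / kk)) <= rho_nm) k <- kk
  }
  k
}

# Module positions in a head: regular k-gon at a random feasible radius and
# rotation (k >= 2), or a point near the center (k == 1). Guarantees the
# pairwise separation and edge margin exactly.
place_modules <- function(k, rho_nm, sep_nm) {
  if (k == 1L) {
    r <- sqrt(stats::runif(1)) * 0.5 * max(rho_nm, 0)
    a <- stats::runif(1, 0, 2 * pi)
    return(cbind(x = r * cos(a), y = r * sin(a)))
  }
  rmin <- sep_nm / (2 * sin(pi / k))
  r <- stats::runif(1, rmin, max(rho_nm, rmin))
  a0 <- stats::runif(1, 0, 2 * pi)
  a <- a0 + 2 * pi * (seq_len(k) - 1) / k
  cbind(x = r * cos(a), y = r * sin(a))
}

# Stamp an anisotropic Gaussian spot (amplitude at the true center) into a
# [y, x, z] volume; center in nm, sigmas in nm. Vectorised over a +/- 4 sigma
# subcube using separable outer products.
stamp_spot <- function(v, center_nm, amp, sigma_xy_nm, sigma_z_nm,
                       voxel_size_nm) {
  d <- dim(v)
  dx <- voxel_size_nm[1]; dz <- voxel_size_nm[3]
  cx <- nm_to_idx(center_nm[1], dx)
  cy <- nm_to_idx(center_nm[2], dx)
  cz <- nm_to_idx(center_nm[3], dz)
  rx <- ceiling(4 * sigma_xy_nm / dx)
  rz <- ceiling(4 * sigma_z_nm / dz)
  xs <- max(1L, floor(cx - rx)):min(d[2], ceiling(cx + rx))
  ys <- max(1L, floor(cy - rx)):min(d[1], ceiling(cy + rx))
  zs <- max(1L, floor(cz - rz)):min(d[3], ceiling(cz + rz))
  if (!length(xs) || !length(ys) || !length(zs)) return(v)
  gx <- exp(-((xs - cx) * dx)^2 / (2 * sigma_xy_nm^2))
  gy <- exp(-((ys - cy) * dx)^2 / (2 * sigma_xy_nm^2))
  gz <- exp(-((zs - cz) * dz)^2 / (2 * sigma_z_nm^2))
  plane <- amp * outer(gy, gx)
  for (j in seq_along(zs)) {
    v[ys, xs, zs[j]] <- v[ys, xs, zs[j]] + plane * gz[j]
  }
  v
}

# Stamp many spots into one channel volume in a single call (one array
# copy at entry, in-place accumulation afterwards).
stamp_spots <- function(v, centers_nm, amps, sigma_xy_nm, sigma_z_nm,
                        voxel_size_nm) {
  d <- dim(v)
  dx <- voxel_size_nm[1]; dz <- voxel_size_nm[3]
  n <- nrow(centers_nm)
  sigma_xy_nm <- rep_len(sigma_xy_nm, n)
  sigma_z_nm <- rep_len(sigma_z_nm, n)
  amps <- rep_len(amps, n)
  for (i in seq_len(n)) {
    cx <- nm_to_idx(centers_nm[i, 1], dx)
    cy <- nm_to_idx(centers_nm[i, 2], dx)
    cz <- nm_to_idx(centers_nm[i, 3], dz)
    rx <- ceiling(4 * sigma_xy_nm[i] / dx)
    rz <- ceiling(4 * sigma_z_nm[i] / dz)
    xs <- max(1L, floor(cx - rx)):min(d[2], ceiling(cx + rx))
    ys <- max(1L, floor(cy - rx)):min(d[1], ceiling(cy + rx))
    zs <- max(1L, floor(cz - rz)):min(d[3], ceiling(cz + rz))
    if (!length(xs) || !length(ys) || !length(zs)) next
    gx <- exp(-((xs - cx) * dx)^2 / (2 * sigma_xy_nm[i]^2))
    gy <- exp(-((ys - cy) * dx)^2 / (2 * sigma_xy_nm[i]^2))
    gz <- exp(-((zs - cz) * dz)^2 / (2 * sigma_z_nm[i]^2))
    plane <- amps[i] * outer(gy, gx)
    for (j in seq_along(zs)) {
      v[ys, xs, zs[j]] <- v[ys, xs, zs[j]] + plane * gz[j]
    }
  }
  v
}

#' Generate a ground-truthed synthetic scene
#'
#' Renders a multi-channel 3D stack: the fill channel as blurred spine-head
#' disks at confocal resolution, every planted nanocluster as a separable
#' anisotropic Gaussian spot (sigma = FWHM / 2.3548 per axis) centered at
#' its ground-truth position, then Poisson + Gaussian read noise, clipped
#' to the 16-bit range. Deterministic for a fixed spec (including seed).
#'
#' @param spec a [scene_spec()].
#' @return list with elements `stack` (an [image_stack]) and `truth`
#'   (list of data.frames `spines`, `clusters`, `pairs`; coordinates in nm,
#'   areas in um^2; `spines` carries a `polygon` list column of head
#'   outlines).
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  ny <- spec$field_size_px[1]; nx <- spec$field_size_px[2]
  nz <- spec$n_sections
  dx <- spec$voxel_size_nm[1]; dz <- spec$voxel_size_nm[3]
  cs <- spec$channel_specs
  nc <- nrow(cs)
  fx_nm <- nx * dx; fy_nm <- ny * dx; fz_nm <- nz * dz

  # --- plant spines ----------------------------------------------------------
  spines <- data.frame(
    id = integer(0), area_um2 = numeric(0), radius_nm = numeric(0),
    x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0)
  )
  if (spec$n_spines > 0) {
    areas <- rlnorm_trunc(spec$n_spines, spec$spine_area_dist)
    radii <- sqrt(areas / pi) * 1000
    edge <- max(radii) + 300
    if (2 * edge >= min(fx_nm, fy_nm)) {
      stop("field too small to contain requested spines at requested separations")
    }
    px <- py <- numeric(spec$n_spines)
    placed <- 0L
    tries <- 0L
    max_tries <- 4000L * spec$n_spines
    while (placed < spec$n_spines && tries < max_tries) {
      tries <- tries + 1L
      cx <- stats::runif(1, edge, fx_nm - edge)
      cy <- stats::runif(1, edge, fy_nm - edge)
      if (edge > fx_nm - edge || edge > fy_nm - edge) break
      ok <- placed == 0L ||
        all((px[seq_len(placed)] - cx)^2 + (py[seq_len(placed)] - cy)^2 >=
              spec$min_spine_spacing_nm^2)
      if (ok) {
        placed <- placed + 1L
        px[placed] <- cx; py[placed] <- cy
      }
    }
    if (placed < spec$n_spines) {
      stop("field too small to contain requested spines at requested separations")
    }
    zc <- stats::runif(spec$n_spines, 0.35 * fz_nm, 0.65 * fz_nm)
    spines <- data.frame(
      id = seq_len(spec$n_spines), area_um2 = areas, radius_nm = radii,
      x_nm = px, y_nm = py, z_nm = zc
    )
  }
  spines$polygon <- lapply(seq_len(nrow(spines)), function(i) {
    a <- seq(0, 2 * pi, length.out = 25L)[-25L]
    cbind(
      x_nm = spines$x_nm[i] + spines$radius_nm[i] * cos(a),
      y_nm = spines$y_nm[i] + spines$radius_nm[i] * sin(a)
    )
  })

  # --- plant clusters --------------------------------------------------------
  post_lab <- cs$label[cs$role == "post_scaffold"]
  pre_labs <- cs$label[cs$role == "pre_scaffold"]
  rec_labs <- cs$label[cs$role == "receptor"]
  clusters <- list()
  pairs <- list()
  next_id <- 1L
  add_cluster <- function(channel, x, y, z, area, spine_id, synaptic) {
    peak <- cs$peak_au[cs$label == channel] * stats::runif(1, 0.8, 1.2)
    cl <- data.frame(
      id = next_id, channel = channel, x_nm = x, y_nm = y, z_nm = z,
      area_um2 = area, peak_au = peak, spine_id = spine_id,
      synaptic = synaptic
    )
    next_id <<- next_id + 1L
    clusters[[length(clusters) + 1L]] <<- cl
    cl$id
  }
  zlim <- c(0.15 * fz_nm, 0.85 * fz_nm)

  for (i in seq_len(nrow(spines))) {
    sp <- spines[i, ]
    rho <- sp$radius_nm - spec$spine_margin_nm
    kmax <- min(max_modules(rho, spec$min_module_sep_nm),
                spec$max_modules_per_spine)
    k <- max(1L, stats::rpois(1, spec$modules_per_um2 * sp$area_um2))
    k <- min(k, kmax)
    mp <- place_modules(k, rho, spec$min_module_sep_nm)
    mz <- clamp(sp$z_nm + stats::rnorm(k, 0, 50), zlim[1], zlim[2])
    cleft_side <- sample(c(-1, 1), 1)
    for (m in seq_len(k)) {
      mx <- sp$x_nm + mp[m, "x"]; my <- sp$y_nm + mp[m, "y"]
      area <- rlnorm_trunc(1, spec$cluster_area_dist)
      pid <- add_cluster(post_lab, mx, my, mz[m], area, sp$id, TRUE)
      # synaptic receptor clusters, laterally offset from the scaffold
      for (rl in rec_labs) {
        if (stats::runif(1) > spec$receptor_occupancy) next
        om <- spec$offset_model[
          spec$offset_model$channel == rl & spec$offset_model$ref == post_lab, ]
        if (!nrow(om)) next
        off <- stats::runif(1, om$lateral_min_nm, om$lateral_max_nm)
        # choose a direction keeping the cluster inside the head margin
        pos <- NULL
        for (t in 1:40) {
          a <- stats::runif(1, 0, 2 * pi)
          cand <- c(mx + off * cos(a), my + off * sin(a))
          if ((cand[1] - sp$x_nm)^2 + (cand[2] - sp$y_nm)^2 <= rho^2) {
            pos <- cand; break
          }
        }
        if (is.null(pos)) {  # point toward the head center
          a <- atan2(sp$y_nm - my, sp$x_nm - mx)
          pos <- c(mx + off * cos(a), my + off * sin(a))
        }
        zr <- clamp(mz[m] + stats::rnorm(1, 0, om$axial_sd_nm), zlim[1], zlim[2])
        rid <- add_cluster(rl, pos[1], pos[2], zr,
                           rlnorm_trunc(1, spec$cluster_area_dist), sp$id, TRUE)
        d3 <- sqrt((pos[1] - mx)^2 + (pos[2] - my)^2 + (zr - mz[m])^2)
        pairs[[length(pairs) + 1L]] <- data.frame(
          id_a = rid, id_b = pid, channel_a = rl, channel_b = post_lab,
          distance_nm = d3, relation = "colocalized"
        )
      }
      # presynaptic cluster across the cleft
      for (pl in pre_labs) {
        if (stats::runif(1) > spec$pre_occupancy) next
        om <- spec$offset_model[
          spec$offset_model$channel == pl & spec$offset_model$ref == post_lab, ]
        if (!nrow(om)) next
        off <- stats::runif(1, om$lateral_min_nm, om$lateral_max_nm)
        a <- atan2(sp$y_nm - my, sp$x_nm - mx) + stats::rnorm(1, 0, 0.7)
        bx <- mx + off * cos(a); by <- my + off * sin(a)
        bz <- clamp(mz[m] + cleft_side * om$axial_gap_nm +
                      stats::rnorm(1, 0, om$axial_sd_nm), zlim[1], zlim[2])
        bid <- add_cluster(pl, bx, by, bz,
                           rlnorm_trunc(1, spec$cluster_area_dist), sp$id, TRUE)
        d3 <- sqrt((bx - mx)^2 + (by - my)^2 + (bz - mz[m])^2)
        pairs[[length(pairs) + 1L]] <- data.frame(
          id_a = pid, id_b = bid, channel_a = post_lab, channel_b = pl,
          distance_nm = d3, relation = "juxtaposed"
        )
      }
    }
    # non-synaptic receptor clusters: inside or just outside the head, far
    # from every scaffold module
    for (rl in rec_labs) {
      n_ns <- stats::rpois(1, spec$nonsynaptic_rate)
      for (q in seq_len(n_ns)) {
        pos <- NULL
        for (t in 1:30) {
          rr <- sqrt(stats::runif(1)) * (sp$radius_nm + 500)
          a <- stats::runif(1, 0, 2 * pi)
          cand <- c(sp$x_nm + rr * cos(a), sp$y_nm + rr * sin(a))
          dmin <- sqrt(min((sp$x_nm + mp[, "x"] - cand[1])^2 +
                             (sp$y_nm + mp[, "y"] - cand[2])^2))
          if (dmin >= 400 &&
              cand[1] > 300 && cand[1] < fx_nm - 300 &&
              cand[2] > 300 && cand[2] < fy_nm - 300) {
            pos <- cand; break
          }
        }
        if (is.null(pos)) next
        zr <- clamp(sp$z_nm + stats::rnorm(1, 0, 100), zlim[1], zlim[2])
        add_cluster(rl, pos[1], pos[2], zr,
                    rlnorm_trunc(1, spec$cluster_area_dist), sp$id, FALSE)
      }
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else data.frame(
    id = integer(0), channel = character(0), x_nm = numeric(0),
    y_nm = numeric(0), z_nm = numeric(0), area_um2 = numeric(0),
    peak_au = numeric(0), spine_id = integer(0), synaptic = logical(0)
  )
  pairs <- if (length(pairs)) do.call(rbind, pairs) else data.frame(
    id_a = integer(0), id_b = integer(0), channel_a = character(0),
    channel_b = character(0), distance_nm = numeric(0), relation = character(0)
  )

  # --- render ----------------------------------------------------------------
  v <- array(0, c(ny, nx, nz, nc))
  for (ci in seq_len(nc)) {
    v[, , , ci] <- cs$background_au[ci]
  }
  fill_i <- which(cs$role == "fill")
  if (nrow(spines)) {
    fill <- array(0, c(ny, nx, nz))
    xs <- idx_to_nm(seq_len(nx), dx)
    ys <- idx_to_nm(seq_len(ny), dx)
    zsec <- idx_to_nm(seq_len(nz), dz)
    for (i in seq_len(nrow(spines))) {
      sp <- spines[i, ]
      xr <- which(abs(xs - sp$x_nm) <= sp$radius_nm)
      yr <- which(abs(ys - sp$y_nm) <= sp$radius_nm)
      zr <- which(abs(zsec - sp$z_nm) <= 300)
      if (!length(xr) || !length(yr) || !length(zr)) next
      in_disk <- outer((ys[yr] - sp$y_nm)^2, (xs[xr] - sp$x_nm)^2, "+") <=
        sp$radius_nm^2
      for (z in zr) {
        fill[yr, xr, z] <- pmax(fill[yr, xr, z], in_disk * cs$peak_au[fill_i])
      }
    }
    sxy <- cs$fwhm_xy_nm[fill_i] * FWHM_TO_SIGMA / dx
    sz <- cs$fwhm_z_nm[fill_i] * FWHM_TO_SIGMA / dz
    fill <- blur_axial(blur_lateral(fill, sxy), sz)
    v[, , , fill_i] <- v[, , , fill_i] + fill
  }
  if (nrow(clusters)) {
    for (ci in seq_len(nc)) {
      if (cs$role[ci] == "fill") next
      sel <- clusters$channel == cs$label[ci]
      if (!any(sel)) next
      s_psf <- cs$fwhm_xy_nm[ci] * FWHM_TO_SIGMA
      s_z <- cs$fwhm_z_nm[ci] * FWHM_TO_SIGMA
      cl <- clusters[sel, ]
      s_int <- sqrt(cl$area_um2 / pi) * 1000 / 2   # intrinsic extent
      v[, , , ci] <- stamp_spots(
        v[, , , ci, drop = TRUE],
        cbind(cl$x_nm, cl$y_nm, cl$z_nm), cl$peak_au,
        sqrt(s_psf^2 + s_int^2), sqrt(s_z^2 + (s_int / 2)^2),
        spec$voxel_size_nm
      )
    }
  }
  # --- noise, applied last ---------------------------------------------------
  nm <- spec$noise_model
  if (isTRUE(nm$poisson)) {
    v[] <- stats::rpois(length(v), pmax(v, 0) * nm$gain) / nm$gain
  }
  if (nm$read_sd_au > 0) {
    v[] <- v + stats::rnorm(length(v), 0, nm$read_sd_au)
  }
  v[] <- round(clamp(v, 0, 65535))

  stack <- image_stack(v, spec$voxel_size_nm, cs$label)
  truth <- list(spines = spines, clusters = clusters, pairs = pairs)
  list(stack = stack, truth = truth)
}

#' Build spine ROIs directly from ground truth
#'
#' Converts planted spine-head outlines into a `spine_rois` object (head
#' disks extruded across all sections), bypassing image-based spine
#' detection. Used to isolate downstream stages from spine finding.
#'
#' @param truth the `truth` element of [generate_scene()].
#' @param stack the matching [image_stack].
#' @return A `spine_rois` object (see [make_spine_rois()]).
#' @export
roi_from_truth <- function(truth, stack) {
  d <- dim(stack$voxels)
  dx <- stack$voxel_size_nm[1]
  lab <- array(0L, d[1:3])
  sp <- truth$spines
  xs <- idx_to_nm(seq_len(d[2]), dx)
  ys <- idx_to_nm(seq_len(d[1]), dx)
  for (i in seq_len(nrow(sp))) {
    xr <- which(abs(xs - sp$x_nm[i]) <= sp$radius_nm[i])
    yr <- which(abs(ys - sp$y_nm[i]) <= sp$radius_nm[i])
    if (!length(xr) || !length(yr)) next
    in_disk <- outer((ys[yr] - sp$y_nm[i])^2, (xs[xr] - sp$x_nm[i])^2, "+") <=
      sp$radius_nm[i]^2
    for (z in seq_len(d[3])) {
      m <- lab[yr, xr, z]
      m[in_disk & m == 0L] <- sp$id[i]
      lab[yr, xr, z] <- m
    }
  }
  info <- data.frame(
    id = sp$id, head_area_um2 = sp$area_um2,
    x_nm = sp$x_nm, y_nm = sp$y_nm, z_nm = sp$z_nm,
    border = FALSE, compactness = 1
  )
  structure(
    list(labels = lab, info = info,
         px_area_um2 = (dx / 1000)^2),
    class = "spine_rois"
  )
}

#' Simulate a calibration bead field
#'
#' Plants pairs (or, in dual-color mode, A-B-A triples) of point emitters at
#' an exact spacing along random in-plane orientations and renders them with
#' the supplied PSF, for testing the peak-to-peak and FWHM operators against
#' known geometry (the synthetic analogue of 50 nm spaced single-color and
#' 70 nm spaced dual-color calibration beads).
#'
#' @param spacing_nm exact emitter spacing (> 0).
#' @param n_pairs number of bead pairs (triples in dual-color mode).
#' @param psf list `(fwhm_xy_nm, fwhm_z_nm)`.
#' @param seed RNG seed.
#' @param dual_color if `TRUE`, render A-B-A triples with the middle emitter
#'   in a second channel.
#' @param px_nm lateral pixel size of the calibration field (default 10 nm;
#'   calibration fields are conventionally sampled finer than scene images).
#' @param peak_au emitter peak amplitude.
#' @param background_au constant background.
#' @param read_sd_au Gaussian read-noise SD (0 = noiseless).
#' @return list `(stack, truth)`; `truth$emitters` holds exact positions,
#'   `truth$pairs` the planted spacings.
#' @export
simulate_bead_field <- function(spacing_nm, n_pairs = 10L,
                                psf = list(fwhm_xy_nm = 50, fwhm_z_nm = 300),
                                seed = 1L, dual_color = FALSE,
                                px_nm = 10, peak_au = 30000,
                                background_au = 200, read_sd_au = 20) {
  if (spacing_nm <= 0) stop("spacing_nm must be > 0")
  with_seed(seed, {
    ext <- if (dual_color) 2 * spacing_nm else spacing_nm
    cell_nm <- ext + 12 * psf$fwhm_xy_nm
    ncol_g <- ceiling(sqrt(n_pairs))
    nrow_g <- ceiling(n_pairs / ncol_g)
    fx <- ncol_g * cell_nm; fy <- nrow_g * cell_nm
    nx <- ceiling(fx / px_nm); ny <- ceiling(fy / px_nm)
    if (ext >= min(fx, fy)) stop("spacing exceeds field")
    em <- list()
    prs <- list()
    eid <- 1L
    for (p in seq_len(n_pairs)) {
      gi <- (p - 1L) %% ncol_g
      gj <- (p - 1L) %/% ncol_g
      cx <- (gi + 0.5) * cell_nm + stats::runif(1, -px_nm, px_nm)
      cy <- (gj + 0.5) * cell_nm + stats::runif(1, -px_nm, px_nm)
      a <- stats::runif(1, 0, 2 * pi)
      ux <- cos(a); uy <- sin(a)
      if (dual_color) {
        pos <- rbind(
          c(cx - spacing_nm * ux, cy - spacing_nm * uy),
          c(cx, cy),
          c(cx + spacing_nm * ux, cy + spacing_nm * uy)
        )
        chs <- c("A647", "A594", "A647")
      } else {
        pos <- rbind(
          c(cx - spacing_nm / 2 * ux, cy - spacing_nm / 2 * uy),
          c(cx + spacing_nm / 2 * ux, cy + spacing_nm / 2 * uy)
        )
        chs <- c("A647", "A647")
      }
      ids <- eid + seq_len(nrow(pos)) - 1L
      em[[p]] <- data.frame(
        id = ids, pair = p, channel = chs,
        x_nm = pos[, 1], y_nm = pos[, 2], z_nm = px_nm / 2,
        angle = a
      )
      for (q in seq_len(nrow(pos) - 1L)) {
        prs[[length(prs) + 1L]] <- data.frame(
          id_a = ids[q], id_b = ids[q + 1L], pair = p,
          distance_nm = spacing_nm, relation = "bead_pair"
        )
      }
      eid <- eid + nrow(pos)
    }
    em <- do.call(rbind, em)
    prs <- do.call(rbind, prs)
    labs <- unique(em$channel)
    v <- array(background_au, c(ny, nx, 1L, length(labs)))
    s_xy <- psf$fwhm_xy_nm * FWHM_TO_SIGMA
    for (ci in seq_along(labs)) {
      ch <- v[, , , ci, drop = TRUE]
      dim(ch) <- c(ny, nx, 1L)
      sel <- which(em$channel == labs[ci])
      for (j in sel) {
        ch <- stamp_spot(ch, c(em$x_nm[j], em$y_nm[j], em$z_nm[j]),
                         peak_au, s_xy, psf$fwhm_z_nm * FWHM_TO_SIGMA,
                         c(px_nm, px_nm, px_nm))
      }
      v[, , 1L, ci] <- ch[, , 1L]
    }
    if (read_sd_au > 0) v[] <- v + stats::rnorm(length(v), 0, read_sd_au)
    v[] <- round(clamp(v, 0, 65535))
    list(
      stack = image_stack(v, c(px_nm, px_nm, px_nm), labs),
      truth = list(emitters = em, pairs = prs)
    )
  })
}

#' Simulate a field of colocalized scaffold-receptor cluster pairs
#'
#' Plants `n_pairs` scaffold clusters on a jittered grid, each with one or
#' more receptor clusters at an exact lateral offset (uniform within the
#' per-channel range, random in-plane direction), rendered with the
#' channel PSFs and the standard noise model. This isolates the distance
#' measurement from spine segmentation, for calibrating center-to-center
#' estimates against planted offsets.
#'
#' @param n_pairs number of scaffold clusters.
#' @param receptor_offsets named list: receptor channel label ->
#'   `c(min_nm, max_nm)` lateral offset range (default one channel,
#'   `GluA2 = c(150, 200)`).
#' @param seed RNG seed.
#' @param voxel_size_nm `(dx, dy, dz)` (default 25, 25, 150).
#' @param n_sections z sections (default 7).
#' @param grid_px grid cell side in pixels (default 32; cells comfortably
#'   contain one pair).
#' @param scaffold_fwhm_nm,receptor_fwhm_nm lateral PSF FWHMs (80 / 50 nm).
#' @param fwhm_z_nm axial FWHM (300 nm).
#' @param peak_au,background_au intensity scale.
#' @param cluster_area_dist planted cluster-area distribution (as in
#'   [scene_spec()]).
#' @param noise_model as in [scene_spec()].
#' @return list `(stack, truth)`; `truth$clusters` has planted centers,
#'   `truth$pairs` the planted receptor-scaffold offsets (3D nm).
#' @export
simulate_pair_field <- function(n_pairs,
                                receptor_offsets = list(GluA2 = c(150, 200)),
                                seed = 1L,
                                voxel_size_nm = c(25, 25, 150),
                                n_sections = 7L,
                                grid_px = 32L,
                                scaffold_fwhm_nm = 80,
                                receptor_fwhm_nm = 50,
                                fwhm_z_nm = 300,
                                peak_au = 33000,
                                background_au = 400,
                                cluster_area_dist = list(
                                  meanlog = log(0.012), sdlog = 0.5,
                                  min = 0.002, max = 0.15
                                ),
                                noise_model = list(
                                  poisson = TRUE, gain = 1, read_sd_au = 100
                                )) {
  stopifnot(n_pairs >= 1)
  with_seed(seed, {
    dx <- voxel_size_nm[1]; dz <- voxel_size_nm[3]
    ncol_g <- ceiling(sqrt(n_pairs))
    nrow_g <- ceiling(n_pairs / ncol_g)
    nx <- ncol_g * grid_px; ny <- nrow_g * grid_px
    fz <- n_sections * dz
    labs <- c("PSD95", names(receptor_offsets))
    v <- array(background_au, c(ny, nx, n_sections, length(labs)))
    s_sc <- scaffold_fwhm_nm * FWHM_TO_SIGMA
    s_rc <- receptor_fwhm_nm * FWHM_TO_SIGMA
    s_z <- fwhm_z_nm * FWHM_TO_SIGMA
    cl <- list(); prs <- list()
    spots <- lapply(labs, function(l) list())  # per-channel stamp queues
    names(spots) <- labs
    cid <- 1L
    for (p in seq_len(n_pairs)) {
      gi <- (p - 1L) %% ncol_g
      gj <- (p - 1L) %/% ncol_g
      cx <- (gi + 0.5) * grid_px * dx + stats::runif(1, -2 * dx, 2 * dx)
      cy <- (gj + 0.5) * grid_px * dx + stats::runif(1, -2 * dx, 2 * dx)
      cz <- stats::runif(1, 0.45 * fz, 0.55 * fz)
      s_int <- sqrt(rlnorm_trunc(1, cluster_area_dist) / pi) * 1000 / 2
      spots[[1]][[length(spots[[1]]) + 1L]] <- c(
        cx, cy, cz, peak_au * stats::runif(1, 0.8, 1.2),
        sqrt(s_sc^2 + s_int^2), sqrt(s_z^2 + (s_int / 2)^2)
      )
      sc_id <- cid
      cl[[length(cl) + 1L]] <- data.frame(
        id = cid, channel = labs[1], x_nm = cx, y_nm = cy, z_nm = cz
      )
      cid <- cid + 1L
      for (ri in seq_along(receptor_offsets)) {
        rng <- receptor_offsets[[ri]]
        off <- stats::runif(1, rng[1], rng[2])
        a <- stats::runif(1, 0, 2 * pi)
        rx <- cx + off * cos(a); ry <- cy + off * sin(a)
        s_int_r <- sqrt(rlnorm_trunc(1, cluster_area_dist) / pi) * 1000 / 2
        spots[[ri + 1L]][[length(spots[[ri + 1L]]) + 1L]] <- c(
          rx, ry, cz, peak_au * stats::runif(1, 0.8, 1.2),
          sqrt(s_rc^2 + s_int_r^2), sqrt(s_z^2 + (s_int_r / 2)^2)
        )
        cl[[length(cl) + 1L]] <- data.frame(
          id = cid, channel = labs[ri + 1L], x_nm = rx, y_nm = ry, z_nm = cz
        )
        prs[[length(prs) + 1L]] <- data.frame(
          id_a = cid, id_b = sc_id, channel_a = labs[ri + 1L],
          channel_b = labs[1], distance_nm = off, relation = "colocalized"
        )
        cid <- cid + 1L
      }
    }
    for (i in seq_along(labs)) {
      if (!length(spots[[i]])) next
      sm <- do.call(rbind, spots[[i]])
      v[, , , i] <- stamp_spots(
        v[, , , i, drop = TRUE], sm[, 1:3, drop = FALSE], sm[, 4],
        sm[, 5], sm[, 6], voxel_size_nm
      )
    }
    if (isTRUE(noise_model$poisson)) {
      v[] <- stats::rpois(length(v), pmax(v, 0) * noise_model$gain) /
        noise_model$gain
    }
    if (noise_model$read_sd_au > 0) {
      v[] <- v + stats::rnorm(length(v), 0, noise_model$read_sd_au)
    }
    v[] <- round(clamp(v, 0, 65535))
    list(
      stack = image_stack(v, voxel_size_nm, labs),
      truth = list(
        clusters = do.call(rbind, cl),
        pairs = do.call(rbind, prs)
      )
    )
  })
}

#' Simulate spine-area time-lapse records around a potentiation stimulus
#'
#' Baseline frames followed by post-stimulus frames at 6-min spacing.
#' Potentiated spines get a sustained relative area increase of
#' `effect_size` immediately after the stimulus; the rest fluctuate around
#' baseline. The generative label is stored for classifier validation.
#'
#' @param n_spines number of spines.
#' @param frac_potentiated fraction of spines given the sustained increase.
#' @param effect_size relative sustained area increase (e.g. 0.5 = +50%).
#' @param noise_sd multiplicative frame-to-frame noise SD (fraction of the
#'   frame's mean area).
#' @param n_frames total frames (baseline + post); must be >= 2.
#' @param seed RNG seed.
#' @param n_baseline number of baseline frames (default 5, i.e. 30 min).
#' @param frame_min_spacing minutes between frames (default 6).
#' @return data.frame with one row per spine per frame: `spine_id`,
#'   `frame`, `t_min`, `phase` (`baseline`/`post`), `area_um2`, and the
#'   generative `class_true` (`potentiated`/`non_responsive`).
#' @export
simulate_timelapse <- function(n_spines, frac_potentiated, effect_size,
                               noise_sd, n_frames, seed = 1L,
                               n_baseline = 5L, frame_min_spacing = 6) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  stopifnot(frac_potentiated >= 0, frac_potentiated <= 1)
  n_baseline <- min(n_baseline, n_frames - 1L)
  with_seed(seed, {
    base <- clamp(stats::rlnorm(n_spines, log(0.5), 0.4), 0.1, 2)
    n_pot <- round(frac_potentiated * n_spines)
    cls <- rep("non_responsive", n_spines)
    if (n_pot > 0) cls[sample.int(n_spines, n_pot)] <- "potentiated"
    recs <- lapply(seq_len(n_spines), function(i) {
      mult <- rep(1, n_frames)
      if (cls[i] == "potentiated") {
        mult[(n_baseline + 1L):n_frames] <- 1 + effect_size
      }
      noise <- if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else 0
      area <- base[i] * mult * (1 + noise)
      data.frame(
        spine_id = i,
        frame = seq_len(n_frames),
        t_min = (seq_len(n_frames) - 1L) * frame_min_spacing,
        phase = c(rep("baseline", n_baseline),
                  rep("post", n_frames - n_baseline)),
        area_um2 = pmax(area, 1e-4),
        class_true = cls[i]
      )
    })
    do.call(rbind, recs)
  })
}
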