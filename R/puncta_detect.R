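#' Local mean + k*SD threshold of a single plane
#'
#' A pixel is foreground iff its intensity strictly exceeds the local mean
#' plus `k` local SDs, computed over a centered `window_px` x `window_px`
#' neighborhood, edge-clipped at the plane borders (windows are not
#' mirrored). The 50 px default window approximately matches the maximum
#' size of a spine head at 25 nm pixels.
#'
#' @param plane numeric matrix.
#' @param window_px window side (>= 3). A window larger than the plane
#'   falls back to global statistics with a warning.
#' @param k SD multiplier (default 2).
#' @return logical matrix of foreground pixels.
#' @export
local_threshold <- function(plane, window_px = 50L, k = 2) {
  stopifnot(is.matrix(plane))
  if (window_px < 3L) stop("window_px must be >= 3")
  if (window_px > nrow(plane) && window_px > ncol(plane)) {
    warning("window larger than plane; falling back to global statistics")
    mu <- mean(plane)
    sd_pop <- sqrt(mean((plane - mu)^2))
    return(plane > mu + k * sd_pop)
  }
  ls <- local_stats(plane, window_px)
  plane > ls$mean + k * ls$sd
}

# Cluster table scaffold
empty_clusters <- function() {
  data.frame(
    id = integer(0), channel = character(0), n_vox = integer(0),
    max_section_px = integer(0), area_um2 = numeric(0),
    x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
    total_intensity = numeric(0), voxels = I(list())
  )
}

cluster_row <- function(id, channel, vox, intens, voxel_size_nm, px_area) {
  per_z <- tabulate(vox[, "z"])
  mx <- max(per_z)
  ct <- centroid_nm(vox, intens, voxel_size_nm)
  data.frame(
    id = id, channel = channel, n_vox = nrow(vox),
    max_section_px = mx, area_um2 = mx * px_area,
    x_nm = unname(ct["x_nm"]), y_nm = unname(ct["y_nm"]),
    z_nm = unname(ct["z_nm"]),
    total_intensity = sum(intens), voxels = I(list(vox))
  )
}

#' Connected-component nanocluster detection with size filters
#'
#' Per-section 8-connected components of a binary volume, linked across z
#' wherever adjacent-section components share at least one (y, x) pixel.
#' A cluster's pixel count is taken on its maximal-area section and its
#' area is that count times the pixel area. Clusters are kept only when
#' the max-section pixel count lies in `[min_px, max_px]` AND the derived
#' area lies in `[min_area_um2, max_area_um2]` (the printed 10--100 px /
#' 0.002--0.15 um^2 filters; at 23--25 nm pixels the lower area bound is
#' non-binding).
#'
#' @param binary logical `[y, x, z]` volume (a matrix is promoted to one
#'   section).
#' @param intensity co-registered intensity volume (for centroids).
#' @param voxel_size_nm `(dx, dy, dz)`.
#' @param channel channel label recorded on the output rows.
#' @param min_px,max_px max-section pixel-count bounds (defaults 10, 100).
#' @param min_area_um2,max_area_um2 area bounds (defaults 0.002, 0.15).
#' @return Cluster data.frame: `id`, `channel`, `n_vox`, `max_section_px`,
#'   `area_um2`, intensity-weighted 3D centroid (`x_nm`, `y_nm`, `z_nm`),
#'   `total_intensity`, and a `voxels` list column of `(y, x, z)` index
#'   matrices.
#' @export
connected_clusters <- function(binary, intensity, voxel_size_nm,
                               channel = "ch1",
                               min_px = 10L, max_px = 100L,
                               min_area_um2 = 0.002, max_area_um2 = 0.15) {
  if (is.matrix(binary)) dim(binary) <- c(dim(binary), 1L)
  if (is.matrix(intensity)) dim(intensity) <- c(dim(intensity), 1L)
  stopifnot(identical(dim(binary), dim(intensity)))
  px_area <- (voxel_size_nm[1] / 1000)^2
  lab <- label_components_3d(binary)
  nlab <- max(lab)
  if (nlab == 0L) return(empty_clusters())
  # vectorised size filter: max-section pixel count per label
  d <- dim(lab)
  pos <- which(lab > 0L)
  zz <- (pos - 1L) %/% (d[1] * d[2]) + 1L
  key <- (lab[pos] - 1L) * d[3] + zz
  cnt <- matrix(tabulate(key, nlab * d[3]), nrow = d[3])
  mx <- cnt[1, ]
  for (z in seq_len(d[3])[-1]) mx <- pmax(mx, cnt[z, ])
  area <- mx * px_area
  keep <- which(mx >= min_px & mx <= max_px &
                  area >= min_area_um2 & area <= max_area_um2)
  if (!length(keep)) return(empty_clusters())
  sel <- lab[pos] %in% keep
  lab2 <- array(0L, d)
  lab2[pos[sel]] <- match(lab[pos[sel]], keep)
  vox <- label_voxels(lab2)
  out <- vector("list", length(keep))
  for (id in seq_along(keep)) {
    vv <- vox[[id]]
    out[[id]] <- cluster_row(
      id, channel, vv, intensity[vv], voxel_size_nm, px_area
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# local maxima restricted to a cluster's voxel set (bounding subcube with
# outside voxels masked to -Inf)
cluster_maxima <- function(intensity, vox, r_xy = 3L, r_z = 2L) {
  ylim <- range(vox[, "y"]); xlim <- range(vox[, "x"]); zlim <- range(vox[, "z"])
  sub <- array(-Inf, c(diff(ylim) + 1L, diff(xlim) + 1L, diff(zlim) + 1L))
  loc <- cbind(vox[, "y"] - ylim[1] + 1L, vox[, "x"] - xlim[1] + 1L,
               vox[, "z"] - zlim[1] + 1L)
  sub[loc] <- intensity[vox]
  mx <- find_maxima_3d(sub, r_xy = r_xy, r_z = r_z, noise = 0)
  if (!nrow(mx)) return(mx)
  mx$y <- mx$y + ylim[1] - 1L
  mx$x <- mx$x + xlim[1] - 1L
  mx$z <- mx$z + zlim[1] - 1L
  mx
}

# ordered-flooding watershed of one cluster's voxels from labelled seeds:
# voxels are visited in decreasing intensity; an unlabelled voxel takes the
# label of its brightest already-labelled 26-neighbor.
watershed_split <- function(vox, intens, seeds_idx) {
  n <- nrow(vox)
  lab <- integer(n)
  lab[seeds_idx] <- seq_along(seeds_idx)
  key <- paste(vox[, "y"], vox[, "x"], vox[, "z"])
  pos <- stats::setNames(seq_len(n), key)
  ord <- order(-intens, vox[, "z"], vox[, "y"], vox[, "x"])
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  for (pass in 1:2) {  # two passes settle voxels brighter than their seed path
    for (i in ord) {
      if (lab[i] > 0L) next
      nb_key <- paste(vox[i, "y"] + offs$dy, vox[i, "x"] + offs$dx,
                      vox[i, "z"] + offs$dz)
      nb <- pos[nb_key]
      nb <- nb[!is.na(nb)]
      nb <- nb[lab[nb] > 0L]
      if (length(nb)) lab[i] <- lab[nb[which.max(intens[nb])]]
    }
  }
  # any voxel still unlabelled joins the nearest seed
  if (any(lab == 0L)) {
    sy <- vox[seeds_idx, , drop = FALSE]
    for (i in which(lab == 0L)) {
      d2 <- (sy[, "y"] - vox[i, "y"])^2 + (sy[, "x"] - vox[i, "x"])^2 +
        (sy[, "z"] - vox[i, "z"])^2
      lab[i] <- which.min(d2)
    }
  }
  lab
}

#' Split touching clusters along dim intensity valleys
#'
#' For each cluster with two or more internal intensity maxima, the
#' straight-line intensity profile between each pair of maxima is sampled
#' (trilinear interpolation at 1 px steps). If the profile minimum falls
#' below the local mean + `k_sep` * SD (computed over a `window_px` window
#' around the cluster center on its central section), the two maxima are
#' deemed separate modules; maxima groups that remain connected by bright
#' ridges stay merged. Qualifying clusters are split by an ordered-flooding
#' watershed seeded at the maxima; voxels are never shared between the
#' resulting clusters.
#'
#' @param intensity `[y, x, z]` intensity volume.
#' @param clusters cluster table from [connected_clusters()].
#' @param voxel_size_nm `(dx, dy, dz)`.
#' @param window_px local-statistics window (default 50).
#' @param k_sep SD multiplier of the separation threshold (default 1.5).
#' @return Cluster table with split clusters replacing their parents
#'   (ids renumbered).
#' @export
split_touching <- function(intensity, clusters, voxel_size_nm,
                           window_px = 50L, k_sep = 1.5) {
  if (is.matrix(intensity)) dim(intensity) <- c(dim(intensity), 1L)
  if (!nrow(clusters)) return(clusters)
  px_area <- (voxel_size_nm[1] / 1000)^2
  out <- list()
  id <- 1L
  for (r in seq_len(nrow(clusters))) {
    vv <- clusters$voxels[[r]]
    mx <- cluster_maxima(intensity, vv)
    split_done <- FALSE
    if (nrow(mx) >= 2L) {
      # local separation threshold at the cluster center
      zc <- round(nm_to_idx(clusters$z_nm[r], voxel_size_nm[3]))
      zc <- clamp(zc, 1L, dim(intensity)[3])
      ls <- local_stats_at(
        intensity[, , zc],
        round(nm_to_idx(clusters$y_nm[r], voxel_size_nm[2])),
        round(nm_to_idx(clusters$x_nm[r], voxel_size_nm[1])), window_px
      )
      sep_thr <- ls$mean + k_sep * ls$sd
      m <- nrow(mx)
      # maxima stay merged when the connecting profile never dips below the
      # threshold; split groups are connected components of "merged" edges
      merged <- diag(TRUE, m)
      for (a in seq_len(m - 1L)) {
        for (b in (a + 1L):m) {
          npts <- max(2L, ceiling(sqrt(
            (mx$y[a] - mx$y[b])^2 + (mx$x[a] - mx$x[b])^2 +
              (mx$z[a] - mx$z[b])^2
          )) + 1L)
          t <- seq(0, 1, length.out = npts)
          prof <- trilinear(
            intensity,
            mx$y[a] + t * (mx$y[b] - mx$y[a]),
            mx$x[a] + t * (mx$x[b] - mx$x[a]),
            mx$z[a] + t * (mx$z[b] - mx$z[a])
          )
          if (min(prof) >= sep_thr) merged[a, b] <- merged[b, a] <- TRUE
        }
      }
      grp <- components_bool(merged)
      if (max(grp) >= 2L) {
        # one seed per group: its brightest maximum
        seeds <- vapply(seq_len(max(grp)), function(g) {
          cand <- which(grp == g)
          cand[which.max(mx$value[cand])]
        }, integer(1))
        key_all <- paste(vv[, "y"], vv[, "x"], vv[, "z"])
        seed_idx <- match(paste(mx$y[seeds], mx$x[seeds], mx$z[seeds]), key_all)
        seed_idx <- seed_idx[!is.na(seed_idx)]
        if (length(seed_idx) >= 2L) {
          part <- watershed_split(vv, intensity[vv], seed_idx)
          for (g in sort(unique(part))) {
            sub <- vv[part == g, , drop = FALSE]
            out[[length(out) + 1L]] <- cluster_row(
              id, clusters$channel[r], sub, intensity[sub],
              voxel_size_nm, px_area
            )
            id <- id + 1L
          }
          split_done <- TRUE
        }
      }
    }
    if (!split_done) {
      row <- clusters[r, ]
      row$id <- id
      id <- id + 1L
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# local mean/sd of a window_px window centered at (y, x), edge-clipped
local_stats_at <- function(plane, y, x, window_px) {
  lo <- ceiling(window_px / 2) - 1L
  hi <- floor(window_px / 2)
  ys <- clamp(y - lo, 1L, nrow(plane)):clamp(y + hi, 1L, nrow(plane))
  xs <- clamp(x - lo, 1L, ncol(plane)):clamp(x + hi, 1L, ncol(plane))
  w <- plane[ys, xs]
  mu <- mean(w)
  list(mean = mu, sd = sqrt(mean((w - mu)^2)))
}

# connected components of a boolean adjacency matrix
components_bool <- function(adj) {
  m <- nrow(adj)
  grp <- integer(m)
  g <- 0L
  for (i in seq_len(m)) {
    if (grp[i] > 0L) next
    g <- g + 1L
    front <- i
    grp[i] <- g
    while (length(front)) {
      nb <- which(colSums(adj[front, , drop = FALSE]) > 0 & grp == 0L)
      grp[nb] <- g
      front <- nb
    }
  }
  grp
}

#' Detect nanoclusters in one channel of a stack
#'
#' Convenience wrapper: per-section local threshold, connected components
#' with the size filters, then valley-based splitting of touching clusters.
#'
#' @param stack an [image_stack].
#' @param channel channel label.
#' @param window_px,k,k_sep,min_px,max_px,min_area_um2,max_area_um2
#'   detection parameters (see [local_threshold()], [connected_clusters()],
#'   [split_touching()]).
#' @param split apply [split_touching()] (default TRUE).
#' @return Cluster table.
#' @export
detect_clusters <- function(stack, channel, window_px = 50L, k = 2,
                            k_sep = 1.5, min_px = 10L, max_px = 100L,
                            min_area_um2 = 0.002, max_area_um2 = 0.15,
                            split = TRUE) {
  v <- get_channel(stack, channel)
  if (is.matrix(v)) dim(v) <- c(dim(v), 1L)
  bin <- array(FALSE, dim(v))
  for (z in seq_len(dim(v)[3])) {
    bin[, , z] <- local_threshold(v[, , z], window_px, k)
  }
  cl <- connected_clusters(
    bin, v, stack$voxel_size_nm, channel,
    min_px, max_px, min_area_um2, max_area_um2
  )
  if (split && nrow(cl)) {
    cl <- split_touching(v, cl, stack$voxel_size_nm, window_px, k_sep)
  }
  cl
}
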