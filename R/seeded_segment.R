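#' 3D local maxima with an anisotropic ellipsoidal neighborhood
#'
#' A voxel is a seed iff it strictly exceeds every voxel of the ellipsoidal
#' neighborhood with radii (`r_xy`, `r_xy`, `r_z`) in (x, y, z), after
#' subtraction of a `noise` floor (0 by default, as for deconvolved data);
#' seeds at or below the floor are discarded. Plateau ties are broken
#' toward the lexicographically smallest (z, y, x) index, so exactly one
#' seed survives per tied plateau within a neighborhood radius.
#'
#' @param v 3-D `[y, x, z]` intensity array (a matrix is promoted to one
#'   section).
#' @param r_xy in-plane neighborhood radius in pixels (default 3).
#' @param r_z axial radius in sections (default 2).
#' @param noise intensity floor subtracted before comparison (default 0).
#' @return data.frame `y`, `x`, `z`, `value`, ordered by (z, y, x).
#' @export
find_maxima_3d <- function(v, r_xy = 3L, r_z = 2L, noise = 0) {
  if (is.matrix(v)) dim(v) <- c(dim(v), 1L)
  d <- dim(v)
  offs <- ellipsoid_offsets(r_xy, r_z)
  # pad with -Inf so borders compare correctly
  pd <- d + c(2L * r_xy, 2L * r_xy, 2L * r_z)
  pad <- array(-Inf, pd)
  pad[r_xy + seq_len(d[1]), r_xy + seq_len(d[2]), r_z + seq_len(d[3])] <- v
  # cheap prescreen: strict/tie-broken max over the 6 face neighbors
  cand <- which(v > noise)
  if (!length(cand)) {
    return(data.frame(y = integer(0), x = integer(0), z = integer(0),
                      value = numeric(0)))
  }
  yy <- (cand - 1L) %% d[1] + 1L
  xx <- ((cand - 1L) %/% d[1]) %% d[2] + 1L
  zz <- (cand - 1L) %/% (d[1] * d[2]) + 1L
  keep <- rep(TRUE, length(cand))
  vals <- v[cand]
  pd12 <- pd[1] * pd[2]
  for (i in seq_len(nrow(offs))) {
    if (!any(keep)) break
    o <- offs[i, ]
    sel <- which(keep)
    nb <- pad[(yy[sel] + r_xy + o[["dy"]]) +
                (xx[sel] + r_xy + o[["dx"]] - 1L) * pd[1] +
                (zz[sel] + r_z + o[["dz"]] - 1L) * pd12]
    if (o[["lex_after"]] == 1L) {
      keep[sel] <- vals[sel] >= nb    # later-index neighbor: >= keeps us
    } else {
      keep[sel] <- vals[sel] > nb     # earlier-index neighbor must be beaten
    }
  }
  out <- data.frame(y = yy[keep], x = xx[keep], z = zz[keep],
                    value = vals[keep])
  out[order(out$z, out$y, out$x), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# offsets of the ellipsoidal neighborhood (excluding the center), with a
# flag telling whether the offset points to a lexicographically later
# (z, y, x) index; cached per (r_xy, r_z)
.offset_cache <- new.env(parent = emptyenv())
ellipsoid_offsets <- function(r_xy, r_z) {
  key <- paste(r_xy, r_z)
  if (!is.null(.offset_cache[[key]])) return(.offset_cache[[key]])
  g <- expand.grid(dy = -r_xy:r_xy, dx = -r_xy:r_xy, dz = -r_z:r_z)
  g <- g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ]
  inside <- (g$dx^2 + g$dy^2) / max(r_xy^2, 1) + g$dz^2 / max(r_z^2, 1) <= 1
  # degenerate radii keep only on-axis neighbors
  if (r_xy == 0) inside <- inside & g$dx == 0 & g$dy == 0
  if (r_z == 0) inside <- inside & g$dz == 0
  g <- g[inside, ]
  # lexicographic order on (z, y, x): later iff dz>0, or dz==0 & dy>0, or
  # dz==0 & dy==0 & dx>0
  m <- cbind(
    dy = g$dy, dx = g$dx, dz = g$dz,
    lex_after = as.integer((g$dz > 0) | (g$dz == 0 & g$dy > 0) |
                             (g$dz == 0 & g$dy == 0 & g$dx > 0))
  )
  .offset_cache[[key]] <- m
  m
}

#' Seeded 3D region growing of segmented objects
#'
#' For each seed an object threshold is computed as
#' `max(local_thresh, seed_intensity * exp(-sd_gauss^2 / 2))` — the seed's
#' spot, modelled as a Gaussian, is cut at `sd_gauss` spatial SDs from its
#' center (the printed SD multiplier of 1.5 for the Gaussian fit and
#' threshold calculation). Objects are grown
#' from all seeds simultaneously (wave-synchronous BFS over 26-connected
#' voxels) over voxels at or above the claiming seed's threshold, clipped
#' to `max_radius_px` in XY from that seed; a contested voxel goes to the
#' seed whose front reaches it first, ties to the brighter seed. Objects
#' outside `[min_vox, max_vox]` voxels are discarded.
#'
#' @param v 3-D `[y, x, z]` intensity array (16-bit AU scale).
#' @param seeds data.frame from [find_maxima_3d()].
#' @param voxel_size_nm `(dx, dy, dz)`.
#' @param channel channel label recorded on the output rows.
#' @param local_thresh base object threshold in AU, within `[0, 65535]`
#'   (the working regime is 10000--20000; default 15000, the midpoint).
#' @param max_radius_px maximum XY radius of an object from its seed
#'   (default 8).
#' @param sd_gauss SD multiplier of the seed-relative threshold
#'   (default 1.5).
#' @param min_vox,max_vox object voxel-count bounds (defaults 3, 20000).
#' @return Cluster table (same shape as [connected_clusters()]) with one
#'   row per surviving object; every object contains its seed and objects
#'   are pairwise disjoint.
#' @export
grow_objects <- function(v, seeds, voxel_size_nm, channel = "ch1",
                         local_thresh = 15000, max_radius_px = 8L,
                         sd_gauss = 1.5, min_vox = 3L, max_vox = 20000L) {
  if (is.matrix(v)) dim(v) <- c(dim(v), 1L)
  if (local_thresh < 0 || local_thresh > 65535) {
    stop("local_thresh outside [0, 65535]")
  }
  d <- dim(v)
  n_seeds <- nrow(seeds)
  if (!n_seeds) return(empty_clusters())
  px_area <- (voxel_size_nm[1] / 1000)^2
  thr <- pmax(local_thresh, seeds$value * exp(-sd_gauss^2 / 2))
  lab <- array(0L, d)
  alive <- seeds$value >= thr
  front_idx <- which(alive)
  lin <- function(y, x, z) y + (x - 1L) * d[1] + (z - 1L) * d[1] * d[2]
  for (s in front_idx) {
    lab[lin(seeds$y[s], seeds$x[s], seeds$z[s])] <- s
  }
  fy <- seeds$y[front_idx]; fx <- seeds$x[front_idx]; fz <- seeds$z[front_idx]
  fl <- front_idx
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  while (length(fl)) {
    cy <- cx <- cz <- cl <- integer(0)
    for (i in seq_len(nrow(offs))) {
      ny <- fy + offs$dy[i]; nx2 <- fx + offs$dx[i]; nz2 <- fz + offs$dz[i]
      ok <- ny >= 1L & ny <= d[1] & nx2 >= 1L & nx2 <= d[2] &
        nz2 >= 1L & nz2 <= d[3]
      if (!any(ok)) next
      ny <- ny[ok]; nx2 <- nx2[ok]; nz2 <- nz2[ok]; ll <- fl[ok]
      li <- lin(ny, nx2, nz2)
      free <- lab[li] == 0L
      if (!any(free)) next
      ny <- ny[free]; nx2 <- nx2[free]; nz2 <- nz2[free]; ll <- ll[free]
      q <- v[lin(ny, nx2, nz2)] >= thr[ll] &
        (ny - seeds$y[ll])^2 + (nx2 - seeds$x[ll])^2 <= max_radius_px^2
      if (!any(q)) next
      cy <- c(cy, ny[q]); cx <- c(cx, nx2[q]); cz <- c(cz, nz2[q])
      cl <- c(cl, ll[q])
    }
    if (!length(cy)) break
    # resolve same-wave contests: brighter seed wins
    ord <- order(-seeds$value[cl], cl)
    cy <- cy[ord]; cx <- cx[ord]; cz <- cz[ord]; cl <- cl[ord]
    li <- lin(cy, cx, cz)
    first <- !duplicated(li)
    li <- li[first]; cl <- cl[first]
    still_free <- lab[li] == 0L
    li <- li[still_free]; cl <- cl[still_free]
    lab[li] <- cl
    fy <- (li - 1L) %% d[1] + 1L
    fx <- ((li - 1L) %/% d[1]) %% d[2] + 1L
    fz <- (li - 1L) %/% (d[1] * d[2]) + 1L
    fl <- cl
  }
  out <- list()
  id <- 1L
  pos <- which(lab > 0L)
  if (!length(pos)) return(empty_clusters())
  labs_at <- lab[pos]
  yy <- (pos - 1L) %% d[1] + 1L
  xx <- ((pos - 1L) %/% d[1]) %% d[2] + 1L
  zz <- (pos - 1L) %/% (d[1] * d[2]) + 1L
  for (s in sort(unique(labs_at))) {
    sel <- labs_at == s
    nvx <- sum(sel)
    if (nvx < min_vox || nvx > max_vox) next
    vv <- cbind(y = yy[sel], x = xx[sel], z = zz[sel])
    row <- cluster_row(id, channel, vv, v[vv], voxel_size_nm, px_area)
    row$seed_y <- seeds$y[s]; row$seed_x <- seeds$x[s]; row$seed_z <- seeds$z[s]
    out[[length(out) + 1L]] <- row
    id <- id + 1L
  }
  if (!length(out)) return(empty_clusters())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Seeded segmentation of one channel of a stack
#'
#' [find_maxima_3d()] followed by [grow_objects()], the per-cluster
#' segmentation path used for distance analysis.
#'
#' @inheritParams grow_objects
#' @param stack an [image_stack].
#' @param channel channel label.
#' @param r_xy,r_z maxima neighborhood radii.
#' @param noise maxima intensity floor.
#' @return Cluster table.
#' @export
segment_seeded <- function(stack, channel, r_xy = 3L, r_z = 2L, noise = 0,
                           local_thresh = 15000, max_radius_px = 8L,
                           sd_gauss = 1.5, min_vox = 3L, max_vox = 20000L) {
  v <- get_channel(stack, channel)
  if (is.matrix(v)) dim(v) <- c(dim(v), 1L)
  # seeds below the growth threshold can never form an object; pre-floor
  # them for speed without changing the result
  seeds <- find_maxima_3d(v, r_xy, r_z, noise = max(noise, local_thresh - 1))
  grow_objects(v, seeds, stack$voxel_size_nm, channel,
               local_thresh, max_radius_px, sd_gauss, min_vox, max_vox)
}
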