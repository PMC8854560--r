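# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Flood-fill labelling of a logical [y, x, z] volume. Connectivity is
# 8-connected in-plane plus the directly-above/below voxel (components in
# adjacent sections merge iff they share an (y, x) pixel, which this
# neighbourhood realizes). Labels numbered by first foreground voxel in
# column-major order.
flood_fill_oracle <- function(bin) {
  d <- dim(bin)
  lab <- array(0L, d)
  nxt <- 1L
  nbr <- rbind(
    expand.grid(dy = -1:1, dx = -1:1, dz = 0),
    c(0, 0, -1), c(0, 0, 1)
  )
  nbr <- nbr[!(nbr$dy == 0 & nbr$dx == 0 & nbr$dz == 0), ]
  for (pos in which(bin)) {
    if (lab[pos] > 0L) next
    # BFS from pos
    queue <- pos
    lab[pos] <- nxt
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      y <- (p - 1L) %% d[1] + 1L
      x <- ((p - 1L) %/% d[1]) %% d[2] + 1L
      z <- (p - 1L) %/% (d[1] * d[2]) + 1L
      for (k in seq_len(nrow(nbr))) {
        yy <- y + nbr$dy[k]; xx <- x + nbr$dx[k]; zz <- z + nbr$dz[k]
        if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] ||
              zz < 1 || zz > d[3]) next
        q <- yy + (xx - 1L) * d[1] + (zz - 1L) * d[1] * d[2]
        if (bin[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
    nxt <- nxt + 1L
  }
  lab
}

# Exhaustive local-maxima scan with the ellipsoidal neighbourhood and the
# lexicographic plateau tie rule: a voxel wins a tie only against
# neighbours at lexicographically later (z, y, x) indices.
maxima_scan_oracle <- function(v, r_xy = 3L, r_z = 2L, noise = 0) {
  d <- dim(v)
  res <- NULL
  for (z in seq_len(d[3])) for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    val <- v[y, x, z]
    if (val <= noise) next
    ok <- TRUE
    for (dz in -r_z:r_z) for (dy in -r_xy:r_xy) for (dx in -r_xy:r_xy) {
      if (dz == 0 && dy == 0 && dx == 0) next
      if ((dx^2 + dy^2) / max(r_xy^2, 1) + dz^2 / max(r_z^2, 1) > 1) next
      yy <- y + dy; xx <- x + dx; zz <- z + dz
      if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] ||
            zz < 1 || zz > d[3]) next
      nb <- v[yy, xx, zz]
      later <- (dz > 0) || (dz == 0 && dy > 0) ||
        (dz == 0 && dy == 0 && dx > 0)
      if (later) {
        if (val < nb) { ok <- FALSE; break }
      } else {
        if (val <= nb) { ok <- FALSE; break }
      }
    }
    if (ok) res <- rbind(res, c(y = y, x = x, z = z, value = val))
  }
  if (is.null(res)) {
    return(data.frame(y = integer(0), x = integer(0), z = integer(0),
                      value = numeric(0)))
  }
  as.data.frame(res)
}

# Quadratic-scan nearest-neighbour distances (A -> closest B), nm inputs.
nn_scan_oracle <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((a$x_nm[i] - b$x_nm)^2 + (a$y_nm[i] - b$y_nm)^2 +
               (a$z_nm[i] - b$z_nm)^2))
  }, numeric(1))
}

# Exhaustive two-sample ECDF maximum-gap statistic.
ecdf_gap_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Closed-form OLS via the normal equations.
ols_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  unname(solve(t(X1) %*% X1, t(X1) %*% y)[, 1])
}

# Small high-SNR spine scene shared by several tests.
small_scene <- function(seed = 1, n_spines = 4L, noise = TRUE) {
  chs <- default_channel_specs()
  spec <- scene_spec(
    field_size_px = c(256L, 256L), n_sections = 9L,
    n_spines = n_spines, seed = seed,
    channel_specs = chs,
    noise_model = if (noise) {
      list(poisson = TRUE, gain = 1, read_sd_au = 100)
    } else {
      list(poisson = FALSE, gain = 1, read_sd_au = 0)
    }
  )
  generate_scene(spec)
}
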