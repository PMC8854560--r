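# Internal helpers shared across modules. All physical coordinates follow the
# package-wide convention: 1-based voxel index i has its center at
# (i - 0.5) * voxel_size_nm, so centroids are unbiased under reflection.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
idx_to_nm <- function(idx, step_nm) (idx - 0.5) * step_nm

#' @noRd
nm_to_idx <- function(nm, step_nm) nm / step_nm + 0.5

# 1-D Gaussian kernel, sigma in samples; radius 3*sigma (>=1).
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D Gaussian blur with edge replication, implemented as
# shift-and-add over the kernel support (vectorised; no per-pixel loops).
blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  for (j in seq_along(k)) {        # along rows (y)
    sh <- j - r - 1L
    out <- out + k[j] * m[clamp(seq_len(ny) + sh, 1L, ny), , drop = FALSE]
  }
  m2 <- matrix(0, ny, nx)
  for (j in seq_along(k)) {        # along columns (x)
    sh <- j - r - 1L
    m2 <- m2 + k[j] * out[, clamp(seq_len(nx) + sh, 1L, nx), drop = FALSE]
  }
  m2
}

# Lateral blur of a [y, x, z] volume, one 2-D blur per section.
blur_lateral <- function(v, sigma) {
  if (sigma <= 0) return(v)
  for (z in seq_len(dim(v)[3])) v[, , z] <- blur2d(v[, , z], sigma)
  v
}

# Axial blur: weighted sum of z-shifted sections with edge replication.
blur_axial <- function(v, sigma_sections) {
  if (sigma_sections <= 0) return(v)
  k <- gauss_kernel(sigma_sections)
  r <- (length(k) - 1L) / 2L
  nz <- dim(v)[3]
  out <- array(0, dim(v))
  for (j in seq_along(k)) {
    sh <- j - r - 1L
    out <- out + k[j] * v[, , clamp(seq_len(nz) + sh, 1L, nz), drop = FALSE]
  }
  out
}

# Edge-clipped local mean and SD over a w x w window, via integral images.
# Returns list(mean, sd, n). Population SD. Window rows i-(ceiling(w/2)-1) ..
# i+floor(w/2), clipped at the plane edges.
local_stats <- function(m, w) {
  ny <- nrow(m); nx <- ncol(m)
  lo <- ceiling(w / 2) - 1L
  hi <- floor(w / 2)
  # integral images padded with a leading zero row/col
  ii <- function(x) {
    s <- rbind(0, apply(x, 2, cumsum))
    t(rbind(0, apply(t(s), 2, cumsum)))  # cumsum along columns of s
  }
  S1 <- ii(m)
  S2 <- ii(m * m)
  y0 <- clamp(seq_len(ny) - lo, 1L, ny); y1 <- clamp(seq_len(ny) + hi, 1L, ny)
  x0 <- clamp(seq_len(nx) - lo, 1L, nx); x1 <- clamp(seq_len(nx) + hi, 1L, nx)
  # box sums via the four-corner rule, outer over rows/cols
  box <- function(S) {
    S[y1 + 1L, x1 + 1L, drop = FALSE] - S[y0, x1 + 1L, drop = FALSE] -
      S[y1 + 1L, x0, drop = FALSE] + S[y0, x0, drop = FALSE]
  }
  n <- outer(y1 - y0 + 1, x1 - x0 + 1)
  mu <- box(S1) / n
  va <- pmax(box(S2) / n - mu^2, 0)
  list(mean = mu, sd = sqrt(va), n = n)
}

# --- connected components ----------------------------------------------------

# 3-D labelling of a logical [y, x, z] volume: 8-connected components per
# section (EBImage::bwlabel) linked across adjacent sections wherever they
# share >= 1 (y, x) pixel, merged with a union-find. Returns an integer
# label volume with labels 1..K (0 = background), renumbered in first-voxel
# (column-major) order for determinism.
label_components_3d <- function(bin) {
  stopifnot(length(dim(bin)) == 3)
  nz <- dim(bin)[3]
  lab <- array(0L, dim(bin))
  offs <- 0L
  per_z_max <- integer(nz)
  for (z in seq_len(nz)) {
    l <- EBImage::bwlabel(bin[, , z] * 1)
    l <- matrix(as.integer(l), nrow(bin))
    mx <- max(l)
    l[l > 0L] <- l[l > 0L] + offs
    lab[, , z] <- l
    per_z_max[z] <- mx
    offs <- offs + mx
  }
  if (offs == 0L) return(lab)
  parent <- seq_len(offs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  ny <- dim(bin)[1]; nx <- dim(bin)[2]
  merge_pairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) return(invisible())
    pr <- unique(cbind(a[sel], b[sel]))
    for (i in seq_len(nrow(pr))) union2(pr[i, 1L], pr[i, 2L])
  }
  for (z in seq_len(nz)) {
    # bwlabel is 4-connected; union diagonal neighbours for 8-connectivity
    l <- lab[, , z]
    merge_pairs(l[-ny, -nx], l[-1, -1])
    merge_pairs(l[-ny, -1], l[-1, -nx])
  }
  for (z in seq_len(nz - 1L)) {
    merge_pairs(lab[, , z], lab[, , z + 1L])
  }
  roots <- vapply(seq_len(offs), find, integer(1))
  # renumber by first voxel occurrence in column-major order
  pos <- which(lab > 0L)
  rl <- roots[lab[pos]]
  map <- integer(offs)
  firsts <- unique(rl)                 # pos is already ascending
  map[firsts] <- seq_along(firsts)
  lab[pos] <- map[rl]
  lab
}

# Per-label voxel sets from a label volume: list of matrices [n, 3] (y, x, z).
label_voxels <- function(lab) {
  pos <- which(lab > 0L)
  if (!length(pos)) return(list())
  d <- dim(lab)
  yy <- (pos - 1L) %% d[1] + 1L
  xx <- ((pos - 1L) %/% d[1]) %% d[2] + 1L
  zz <- (pos - 1L) %/% (d[1] * d[2]) + 1L
  split.data.frame(cbind(y = yy, x = xx, z = zz), lab[pos])
}

# Intensity-weighted centroid of a voxel set in nm.
centroid_nm <- function(vox, intens, voxel_size_nm) {
  w <- intens / sum(intens)
  c(
    x_nm = sum(w * idx_to_nm(vox[, "x"], voxel_size_nm[1])),
    y_nm = sum(w * idx_to_nm(vox[, "y"], voxel_size_nm[2])),
    z_nm = sum(w * idx_to_nm(vox[, "z"], voxel_size_nm[3]))
  )
}

# Trilinear interpolation in a [y, x, z] volume at fractional voxel-center
# coordinates (1-based index space). Out-of-range coordinates are clamped.
trilinear <- function(v, y, x, z) {
  d <- dim(v)
  x <- clamp(x, 1, d[2]); y <- clamp(y, 1, d[1]); z <- clamp(z, 1, d[3])
  x0 <- clamp(floor(x), 1, d[2] - 1L + (d[2] == 1L)); x1 <- pmin(x0 + 1, d[2])
  y0 <- clamp(floor(y), 1, d[1] - 1L + (d[1] == 1L)); y1 <- pmin(y0 + 1, d[1])
  z0 <- clamp(floor(z), 1, d[3] - 1L + (d[3] == 1L)); z1 <- pmin(z0 + 1, d[3])
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(yy, xx, zz) v[cbind(yy, xx, zz)]
  c00 <- at(y0, x0, z0) * (1 - fx) + at(y0, x1, z0) * fx
  c10 <- at(y1, x0, z0) * (1 - fx) + at(y1, x1, z0) * fx
  c01 <- at(y0, x0, z1) * (1 - fx) + at(y0, x1, z1) * fx
  c11 <- at(y1, x0, z1) * (1 - fx) + at(y1, x1, z1) * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

# Shoelace polygon area (vertices [n, 2], columns x, y).
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Run code with a private RNG stream; restores the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
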