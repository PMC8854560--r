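#' Multi-channel anisotropic 3D image stack
#'
#' The core image container: a 4-D intensity array indexed `[y, x, z,
#' channel]` holding 16-bit-range arbitrary units (AU, 0--65535), with
#' physical voxel sizes in nm and channel identity carried by label strings
#' (never by acquisition order). The physical position of the center of
#' 1-based voxel index `i` along an axis with step `s` nm is `(i - 0.5) * s`,
#' so intensity-weighted centroids are unbiased under reflection.
#'
#' @param voxels numeric array `[ny, nx, nz, nc]` (a 3-D array is promoted to
#'   one channel; a matrix to one channel, one section).
#' @param voxel_size_nm numeric `(dx, dy, dz)`; square pixels (`dx == dy`)
#'   are required.
#' @param channel_labels character vector, one label per channel
#'   (e.g. `"PSD95"`, `"Bassoon"`, `"GluA2"`, `"GFP"`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size_nm, channel_labels) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L, 1L)
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(
    length(dim(voxels)) == 4L,
    all(dim(voxels) >= 1L),
    length(voxel_size_nm) == 3L,
    all(voxel_size_nm > 0),
    abs(voxel_size_nm[1] - voxel_size_nm[2]) < 1e-9,
    length(channel_labels) == dim(voxels)[4],
    !anyDuplicated(channel_labels)
  )
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 65535)
    stop("intensities must lie in [0, 65535]")
  structure(
    list(
      voxels = voxels,
      voxel_size_nm = as.numeric(voxel_size_nm),
      channel_labels = as.character(channel_labels)
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "image_stack: %d x %d px, %d sections, %d channel(s) [%s]\n",
    d[1], d[2], d[3], d[4], paste(x$channel_labels, collapse = ", ")
  ))
  cat(sprintf(
    "voxel size: %.3g x %.3g x %.3g nm\n",
    x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3]
  ))
  invisible(x)
}

#' Extract one channel of a stack as a 3-D `[y, x, z]` array
#'
#' @param stack an [image_stack].
#' @param label channel label string.
#' @return numeric 3-D array.
#' @export
get_channel <- function(stack, label) {
  i <- match(label, stack$channel_labels)
  if (is.na(i)) {
    stop(sprintf(
      "channel '%s' not found (have: %s)",
      label, paste(stack$channel_labels, collapse = ", ")
    ))
  }
  stack$voxels[, , , i, drop = TRUE]
}

#' Write a stack to disk as multi-plane 16-bit TIFF plus a JSON sidecar
#'
#' Planes are written z-fastest, then channel; the sidecar (`<path>.json`)
#' records field size, voxel sizes (nm) and channel labels so that
#' [read_stack()] can restore the stack losslessly.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$voxels)
  planes <- vector("list", d[3] * d[4])
  k <- 1L
  for (ci in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      planes[[k]] <- stack$voxels[, , z, ci] / 65535
      k <- k + 1L
    }
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    ny = d[1], nx = d[2], n_sections = d[3], n_channels = d[4],
    voxel_size_nm = stack$voxel_size_nm,
    channel_labels = stack$channel_labels,
    plane_order = "z_fastest_then_channel",
    intensity_units = "AU16"
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Calibration and channel identity come from the JSON sidecar written by
#' [write_stack()]; for foreign TIFFs they can be supplied via the override
#' arguments. A TIFF without any pixel-size source is an error, as physical
#' nm coordinates are required downstream.
#'
#' @param path TIFF path.
#' @param voxel_size_nm optional `(dx, dy, dz)` override.
#' @param channel_labels optional channel label override.
#' @param n_channels optional channel count when no sidecar is present
#'   (planes are divided as z-fastest).
#' @return An [image_stack].
#' @export
read_stack <- function(path, voxel_size_nm = NULL, channel_labels = NULL,
                       n_channels = NULL) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(planes)) planes <- list(planes)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  if (is.null(voxel_size_nm)) voxel_size_nm <- meta$voxel_size_nm
  if (is.null(voxel_size_nm)) {
    stop("no pixel-size calibration: supply voxel_size_nm or a JSON sidecar")
  }
  nc <- n_channels
  if (is.null(nc)) nc <- meta$n_channels
  if (is.null(nc)) nc <- 1L
  np <- length(planes)
  if (np %% nc != 0) stop("plane count is not divisible by channel count")
  nz <- np / nc
  if (is.null(channel_labels)) channel_labels <- meta$channel_labels
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nc))
  d <- dim(planes[[1]])
  v <- array(0, c(d[1], d[2], nz, nc))
  k <- 1L
  for (ci in seq_len(nc)) {
    for (z in seq_len(nz)) {
      v[, , z, ci] <- round(planes[[k]] * 65535)
      k <- k + 1L
    }
  }
  image_stack(v, voxel_size_nm, channel_labels)
}

#' Write result tables as CSV with stable column order
#'
#' Units are part of the contract: distances and centroid coordinates in nm,
#' areas in square micrometres, counts as integers. Writes a header-only
#' file for empty inputs.
#'
#' @param records a data.frame (cluster table, spine-record table or
#'   distance-pair table). List columns (voxel sets) are dropped.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(records, path) {
  stopifnot(is.data.frame(records))
  keep <- !vapply(records, is.list, logical(1))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_tables()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_tables <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
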