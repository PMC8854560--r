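#' Center-to-center 3D distances between two object sets
#'
#' All geometry is done on physical nm coordinates (the 6x z/xy voxel
#' anisotropy is absorbed when centroids are computed, never in index
#' space). Two modes: `"nearest_neighbor"` reports, for every A object,
#' the distance to its closest B object; `"colocalized_only"` reports
#' distances only for A--B pairs passing the colocalization rule
#' (shared voxel or center distance below `coloc_dist_nm`), the mode used
#' for scaffold--receptor and intra-compartment measurements.
#'
#' @param objects_a,objects_b cluster tables with `x_nm`, `y_nm`, `z_nm`
#'   (and `voxels` for the overlap rule).
#' @param mode `"nearest_neighbor"` or `"colocalized_only"`.
#' @param coloc_dist_nm colocalization distance cutoff (default 250 nm).
#' @param coloc_mode `"overlap"`, `"distance"` or `"either"` (default).
#' @return data.frame `id_a`, `id_b`, `distance_nm`, `relation`.
#' @export
center_to_center <- function(objects_a, objects_b,
                             mode = c("nearest_neighbor", "colocalized_only"),
                             coloc_dist_nm = 250, coloc_mode = "either") {
  mode <- match.arg(mode)
  empty <- data.frame(id_a = integer(0), id_b = integer(0),
                      distance_nm = numeric(0), relation = character(0))
  if (!nrow(objects_a) || !nrow(objects_b)) return(empty)
  dm <- cross_dist(objects_a, objects_b)
  if (mode == "nearest_neighbor") {
    j <- apply(dm, 1, which.min)
    return(data.frame(
      id_a = objects_a$id, id_b = objects_b$id[j],
      distance_nm = dm[cbind(seq_len(nrow(objects_a)), j)],
      relation = "nearest_neighbor"
    ))
  }
  hit <- dm <= coloc_dist_nm
  if (coloc_mode == "overlap") hit[] <- FALSE
  if (coloc_mode %in% c("overlap", "either") &&
      "voxels" %in% names(objects_a) && "voxels" %in% names(objects_b)) {
    # voxel overlap implies nearby centroids; only candidates within a
    # generous 1 um are checked explicitly
    cand <- which(!hit & dm <= 1000, arr.ind = TRUE)
    for (k in seq_len(nrow(cand))) {
      r <- cand[k, 1]; j <- cand[k, 2]
      if (clusters_overlap(objects_a$voxels[[r]], objects_b$voxels[[j]])) {
        hit[r, j] <- TRUE
      }
    }
  }
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  res <- data.frame(
    id_a = objects_a$id[idx[, 1]], id_b = objects_b$id[idx[, 2]],
    distance_nm = dm[idx], relation = "colocalized_only"
  )
  res <- res[order(res$id_a, res$id_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gaussian-fit FWHM of a line intensity profile
#'
#' Least-squares fit of amplitude, center, sigma and baseline to a
#' single-peaked profile; FWHM = 2.3548 sigma. Non-convergent or
#' degenerate fits are flagged (`NA` with attribute `flagged = TRUE`) so
#' callers exclude them from averages.
#'
#' @param profile numeric intensity profile.
#' @param spacing_nm sample spacing along the line in nm.
#' @return FWHM in nm (with attributes `center_nm`, `sigma_nm`), or
#'   flagged `NA`.
#' @export
fwhm_from_profile <- function(profile, spacing_nm) {
  x <- (seq_along(profile) - 1) * spacing_nm
  fit <- fit_gaussians(x, profile, n_peaks = 1L)
  if (is.null(fit)) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  out <- 2.3548 * fit$sigma
  attr(out, "center_nm") <- fit$centers
  attr(out, "sigma_nm") <- fit$sigma
  attr(out, "flagged") <- FALSE
  out
}

# shared-sigma multi-Gaussian + baseline least-squares fit; returns
# list(centers, sigma, amps, baseline, rss) or NULL on failure
fit_gaussians <- function(x, y, n_peaks, centers0 = NULL) {
  if (max(y) - min(y) <= 0) return(NULL)
  if (is.null(centers0)) {
    w <- pmax(y - min(y), 0)
    if (sum(w) == 0) return(NULL)
    cw <- cumsum(w) / sum(w)
    qs <- (seq_len(n_peaks) - 0.5) / n_peaks
    centers0 <- vapply(qs, function(q) x[which.min(abs(cw - q))], numeric(1))
  }
  w <- pmax(y - min(y), 0)
  sigma0 <- sqrt(sum(w * (x - sum(w * x) / sum(w))^2) / sum(w)) /
    max(1, n_peaks)
  sigma0 <- max(sigma0, diff(range(x)) / (20 * n_peaks))
  start <- c(
    stats::setNames(centers0, paste0("c", seq_len(n_peaks))),
    sigma = sigma0,
    stats::setNames(rep(max(y) - min(y), n_peaks),
                    paste0("a", seq_len(n_peaks))),
    b = min(y)
  )
  model <- function(p) {
    m <- rep(p[["b"]], length(x))
    for (i in seq_len(n_peaks)) {
      m <- m + p[[paste0("a", i)]] *
        exp(-(x - p[[paste0("c", i)]])^2 / (2 * p[["sigma"]]^2))
    }
    m
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = as.list(start),
      fn = function(p) y - model(p),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$info %in% c(0, 9)) return(NULL)
  p <- fit$par
  centers <- unlist(p[paste0("c", seq_len(n_peaks))])
  amps <- unlist(p[paste0("a", seq_len(n_peaks))])
  sigma <- abs(p[["sigma"]])
  if (any(amps <= 0) || sigma <= 0 ||
      any(centers < min(x) - diff(range(x)) |
            centers > max(x) + diff(range(x)))) {
    return(NULL)
  }
  ord <- order(centers)
  list(centers = centers[ord], sigma = sigma, amps = amps[ord],
       baseline = p[["b"]], rss = sum(fit$fvec^2))
}

#' Peak-to-peak distances from a multi-peak line profile
#'
#' Shared-width multi-Gaussian fit (the peaks share one PSF); adjacent
#' fitted-center separations are returned. If fewer resolvable maxima than
#' `n_peaks` are found the result is flagged.
#'
#' @param profile numeric intensity profile crossing `n_peaks` maxima.
#' @param n_peaks expected number of peaks.
#' @param spacing_nm sample spacing in nm.
#' @return numeric vector of adjacent separations in nm (attribute
#'   `flagged`), or flagged `NA` on failure.
#' @export
peak_to_peak <- function(profile, n_peaks, spacing_nm) {
  x <- (seq_along(profile) - 1) * spacing_nm
  fit <- fit_gaussians(x, profile, n_peaks = n_peaks)
  flagged_na <- function() {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    out
  }
  if (is.null(fit)) return(flagged_na())
  seps <- diff(fit$centers)
  # unresolved peaks collapse onto each other
  if (n_peaks > 1 && any(seps < spacing_nm)) return(flagged_na())
  attr(seps, "flagged") <- FALSE
  attr(seps, "centers_nm") <- fit$centers
  seps
}

# bilinear profile sample along a 2-D segment, 5 nm default step
line_profile <- function(plane, p0_nm, p1_nm, px_nm, step_nm = 5) {
  len <- sqrt(sum((p1_nm - p0_nm)^2))
  t <- seq(0, 1, by = step_nm / len)
  xs <- nm_to_idx(p0_nm[1] + t * (p1_nm[1] - p0_nm[1]), px_nm)
  ys <- nm_to_idx(p0_nm[2] + t * (p1_nm[2] - p0_nm[2]), px_nm)
  v <- array(plane, c(dim(plane), 1L))
  trilinear(v, ys, xs, rep(1, length(xs)))
}

#' Chromatic offsets from multi-labeled calibration puncta
#'
#' For each punctum and channel, four line profiles through the punctum
#' center (at 0, 45, 90 and 135 degrees) are sampled and Gaussian-fitted;
#' per channel pair, the fitted peak positions are differenced per line,
#' giving the projection of the inter-channel shift on each line
#' direction, and the 2D lateral offset vector is recovered by least
#' squares over the four projections. Axially, a single z-profile through
#' the center is fitted per channel and peak positions differenced.
#' Puncta missing a channel are skipped.
#'
#' @param stack an [image_stack] with the punctum visible in every channel
#'   of interest.
#' @param centers_nm data.frame `x_nm`, `y_nm` (one row per punctum;
#'   approximate centers, e.g. detected maxima of the reference channel).
#' @param channels channel labels to compare (default: all).
#' @param halfwidth_nm profile half-length (default 500 nm).
#' @return list with `per_punctum` (punctum, channel pair, `dx_nm`,
#'   `dy_nm`, `lateral_nm`, `axial_nm`) and `summary` (per pair mean and
#'   SD of lateral and axial offsets).
#' @export
chromatic_offsets <- function(stack, centers_nm, channels = NULL,
                              halfwidth_nm = 500) {
  if (is.null(channels)) channels <- stack$channel_labels
  px <- stack$voxel_size_nm[1]
  dz <- stack$voxel_size_nm[3]
  angles <- c(0, 45, 90, 135) * pi / 180
  per <- list()
  if (!nrow(centers_nm)) {
    return(list(per_punctum = data.frame(), summary = data.frame()))
  }
  for (p in seq_len(nrow(centers_nm))) {
    cx <- centers_nm$x_nm[p]; cy <- centers_nm$y_nm[p]
    # per channel: fitted peak position along each line (signed, nm from
    # line start) and axial peak
    peaks <- list()
    ok <- TRUE
    for (ch in channels) {
      v <- get_channel(stack, ch)
      if (is.matrix(v)) dim(v) <- c(dim(v), 1L)
      zbest <- which.max(vapply(seq_len(dim(v)[3]), function(z) {
        trilinear(v, nm_to_idx(cy, px), nm_to_idx(cx, px), z)
      }, numeric(1)))
      pk <- numeric(length(angles))
      for (ai in seq_along(angles)) {
        u <- c(cos(angles[ai]), sin(angles[ai]))
        p0 <- c(cx, cy) - halfwidth_nm * u
        p1 <- c(cx, cy) + halfwidth_nm * u
        prof <- line_profile(v[, , zbest], p0, p1, px)
        fit <- fit_gaussians((seq_along(prof) - 1) * 5, prof, 1L)
        if (is.null(fit)) { ok <- FALSE; break }
        pk[ai] <- fit$centers - halfwidth_nm  # signed offset from center
      }
      if (!ok) break
      zpk <- NA_real_
      if (dim(v)[3] >= 3) {
        zprof <- vapply(seq_len(dim(v)[3]), function(z) {
          trilinear(v, nm_to_idx(cy, px), nm_to_idx(cx, px), z)
        }, numeric(1))
        zfit <- fit_gaussians(idx_to_nm(seq_along(zprof), dz), zprof, 1L)
        if (!is.null(zfit)) zpk <- zfit$centers
      }
      peaks[[ch]] <- list(lateral = pk, axial = zpk)
    }
    if (!ok) next  # punctum missing a usable channel
    A <- cbind(cos(angles), sin(angles))
    for (i in seq_along(channels)[-length(channels)]) {
      for (j in (i + 1):length(channels)) {
        proj <- peaks[[channels[j]]]$lateral - peaks[[channels[i]]]$lateral
        sol <- stats::lm.fit(A, proj)$coefficients
        ax <- peaks[[channels[j]]]$axial - peaks[[channels[i]]]$axial
        per[[length(per) + 1L]] <- data.frame(
          punctum = p,
          pair = paste(channels[i], channels[j], sep = "-"),
          dx_nm = sol[1], dy_nm = sol[2],
          lateral_nm = sqrt(sum(sol^2)),
          axial_nm = ax
        )
      }
    }
  }
  if (!length(per)) {
    return(list(per_punctum = data.frame(), summary = data.frame()))
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  agg <- do.call(rbind, lapply(split(per, per$pair), function(d) {
    data.frame(
      pair = d$pair[1], n = nrow(d),
      lateral_mean_nm = mean(d$lateral_nm), lateral_sd_nm = stats::sd(d$lateral_nm),
      axial_mean_nm = mean(d$axial_nm), axial_sd_nm = stats::sd(d$axial_nm)
    )
  }))
  rownames(agg) <- NULL
  list(per_punctum = per, summary = agg)
}
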