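#' Assign clusters to spine-head ROIs
#'
#' Postsynaptic channels (scaffold, receptors) use rule `"fully_within"`:
#' every voxel of the cluster must lie inside the ROI mask of its section.
#' Presynaptic channels use `"partial_overlap"`: at least one voxel per
#' occupied section must overlap the ROI. The rule is verified
#' independently in every z-section the cluster occupies. A cluster maps
#' to at most one spine; when it overlaps several ROIs the
#' largest-overlap spine wins.
#'
#' @param clusters cluster table ([connected_clusters()] /
#'   [grow_objects()]).
#' @param spine_rois a `spine_rois` object.
#' @param rule `"fully_within"` or `"partial_overlap"`.
#' @return The cluster table with an added integer `spine_id` column
#'   (`NA` = unassigned).
#' @export
assign_to_spines <- function(clusters, spine_rois, rule = "fully_within") {
  if (!rule %in% c("fully_within", "partial_overlap")) {
    stop(sprintf("unknown rule '%s'", rule))
  }
  lab <- spine_rois$labels
  sid <- rep(NA_integer_, nrow(clusters))
  for (r in seq_len(nrow(clusters))) {
    vv <- clusters$voxels[[r]]
    hits <- lab[vv]
    zs <- vv[, "z"]
    cand <- unique(hits[hits > 0L])
    best <- NA_integer_
    best_ov <- 0L
    for (s in cand) {
      ok <- TRUE
      for (z in unique(zs)) {
        inz <- hits[zs == z]
        if (rule == "fully_within") {
          if (!all(inz == s)) { ok <- FALSE; break }
        } else {
          if (!any(inz == s)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        ov <- sum(hits == s)
        if (ov > best_ov) { best <- s; best_ov <- ov }
      }
    }
    sid[r] <- best
  }
  clusters$spine_id <- sid
  clusters
}

#' Pair juxtaposed pre- and postsynaptic clusters
#'
#' Mutual-nearest-neighbor pairing of postsynaptic scaffold clusters with
#' presynaptic clusters on 3D center distance, kept only below
#' `max_dist_nm`. Unpaired clusters are not dropped by callers; they are
#' simply absent from the pair list (non-juxtaposed).
#'
#' @param post_clusters,pre_clusters cluster tables with nm centroids.
#' @param max_dist_nm juxtaposition distance cutoff (default 500 nm,
#'   bracketing measured trans-synaptic distances with margin).
#' @return data.frame `post_id`, `pre_id`, `distance_nm`.
#' @export
pair_synapses <- function(post_clusters, pre_clusters, max_dist_nm = 500) {
  if (!nrow(post_clusters) || !nrow(pre_clusters)) {
    return(data.frame(post_id = integer(0), pre_id = integer(0),
                      distance_nm = numeric(0)))
  }
  dm <- cross_dist(post_clusters, pre_clusters)
  nn_b <- apply(dm, 1, which.min)   # for each post, nearest pre
  nn_a <- apply(dm, 2, which.min)   # for each pre, nearest post
  keep <- which(nn_a[nn_b] == seq_len(nrow(post_clusters)) &
                  dm[cbind(seq_len(nrow(post_clusters)), nn_b)] <= max_dist_nm)
  data.frame(
    post_id = post_clusters$id[keep],
    pre_id = pre_clusters$id[nn_b[keep]],
    distance_nm = dm[cbind(keep, nn_b[keep])]
  )
}

cross_dist <- function(a, b) {
  outer(a$x_nm, b$x_nm, "-")^2 + outer(a$y_nm, b$y_nm, "-")^2 +
    outer(a$z_nm, b$z_nm, "-")^2 -> d2
  sqrt(d2)
}

# voxel-overlap test between two clusters
clusters_overlap <- function(va, vb) {
  any(paste(va[, "y"], va[, "x"], va[, "z"]) %in%
        paste(vb[, "y"], vb[, "x"], vb[, "z"]))
}

#' Classify receptor clusters as synaptic or non-synaptic
#'
#' A receptor cluster is synaptic iff it colocalizes with a scaffold
#' cluster that belongs to a juxtaposed synapse pair; otherwise it is
#' non-synaptic. Colocalization is >= 1 shared voxel (`"overlap"`), center
#' distance <= `coloc_dist_nm` (`"distance"`, default 250 nm), or either
#' (`"either"`, the default mode).
#'
#' @param receptor_clusters,scaffold_clusters cluster tables.
#' @param synapse_pairs output of [pair_synapses()].
#' @param coloc_mode `"overlap"`, `"distance"` or `"either"`.
#' @param coloc_dist_nm distance fallback cutoff (default 250 nm).
#' @return receptor table with added logical `synaptic` column and
#'   `partner_id` (the scaffold cluster id, `NA` if none).
#' @export
classify_receptor_clusters <- function(receptor_clusters, scaffold_clusters,
                                       synapse_pairs,
                                       coloc_mode = "either",
                                       coloc_dist_nm = 250) {
  stopifnot(coloc_mode %in% c("overlap", "distance", "either"))
  n <- nrow(receptor_clusters)
  receptor_clusters$synaptic <- logical(n)
  receptor_clusters$partner_id <- rep(NA_integer_, n)
  jux <- scaffold_clusters[scaffold_clusters$id %in% synapse_pairs$post_id, ,
                           drop = FALSE]
  if (!n || !nrow(jux)) return(receptor_clusters)
  dm <- cross_dist(receptor_clusters, jux)
  for (r in seq_len(n)) {
    ord <- order(dm[r, ])
    for (j in ord) {
      by_dist <- dm[r, j] <= coloc_dist_nm
      hit <- switch(coloc_mode,
        distance = by_dist,
        overlap = clusters_overlap(receptor_clusters$voxels[[r]],
                                   jux$voxels[[j]]),
        either = by_dist || clusters_overlap(receptor_clusters$voxels[[r]],
                                             jux$voxels[[j]])
      )
      if (hit) {
        receptor_clusters$synaptic[r] <- TRUE
        receptor_clusters$partner_id[r] <- jux$id[j]
        break
      }
      if (coloc_mode == "distance" && !by_dist) break  # sorted: no later hit
    }
  }
  receptor_clusters
}

#' Per-spine records of synaptic and non-synaptic cluster counts
#'
#' @param assigned named list of cluster tables (one per channel) that
#'   carry `spine_id` and, for receptor channels, `synaptic`.
#' @param spine_rois the `spine_rois` the clusters were assigned against.
#' @return data.frame with one row per spine and per-channel columns
#'   `n_<channel>` (synaptic / total assigned for scaffold channels),
#'   `n_<channel>_nonsyn` for receptor channels.
#' @export
spine_records <- function(assigned, spine_rois) {
  info <- spine_rois$info
  rec <- data.frame(spine_id = info$id, head_area_um2 = info$head_area_um2)
  for (ch in names(assigned)) {
    cl <- assigned[[ch]]
    syn <- if ("synaptic" %in% names(cl)) cl$synaptic else TRUE
    tot <- tabulate(cl$spine_id[!is.na(cl$spine_id)], nbins = nrow(info))
    nsy <- tabulate(cl$spine_id[!is.na(cl$spine_id) & syn], nbins = nrow(info))
    rec[[paste0("n_", ch)]] <- nsy
    if ("synaptic" %in% names(cl)) {
      rec[[paste0("n_", ch, "_nonsyn")]] <- tot - nsy
    }
  }
  rec
}

#' Summary tables over spine records
#'
#' Occupancy (percent of spines containing >= 1 cluster per channel), the
#' distribution of spines by cluster count (1, 2, 3, 4+), and for receptor
#' channels the split between spines with only synaptic clusters vs both
#' synaptic and non-synaptic.
#'
#' @param records output of [spine_records()].
#' @return list of data.frames: `occupancy_pct`, `count_distribution_pct`,
#'   `synaptic_only_pct`.
#' @export
summarize_spines <- function(records) {
  if (!nrow(records)) {
    return(list(
      occupancy_pct = data.frame(channel = character(0), pct = numeric(0)),
      count_distribution_pct = data.frame(),
      synaptic_only_pct = data.frame()
    ))
  }
  chans <- sub("^n_", "", grep("^n_[^_]+$", names(records), value = TRUE))
  occ <- data.frame(
    channel = chans,
    pct = vapply(chans, function(ch) {
      100 * mean(records[[paste0("n_", ch)]] > 0)
    }, numeric(1))
  )
  cd <- do.call(rbind, lapply(chans, function(ch) {
    n <- records[[paste0("n_", ch)]]
    n <- n[n > 0]
    if (!length(n)) {
      return(data.frame(channel = ch, count = c("1", "2", "3", "4+"),
                        pct = 0))
    }
    bins <- cut(n, c(0.5, 1.5, 2.5, 3.5, Inf), labels = c("1", "2", "3", "4+"))
    data.frame(channel = ch, count = levels(bins),
               pct = 100 * as.numeric(table(bins)) / length(n))
  }))
  so <- do.call(rbind, lapply(chans, function(ch) {
    ns_col <- paste0("n_", ch, "_nonsyn")
    if (!ns_col %in% names(records)) return(NULL)
    syn <- records[[paste0("n_", ch)]]
    nsn <- records[[ns_col]]
    with_syn <- syn > 0
    if (!any(with_syn)) {
      return(data.frame(channel = ch, only_synaptic_pct = NA_real_,
                        both_pct = NA_real_))
    }
    data.frame(
      channel = ch,
      only_synaptic_pct = 100 * mean(nsn[with_syn] == 0),
      both_pct = 100 * mean(nsn[with_syn] > 0)
    )
  }))
  list(occupancy_pct = occ, count_distribution_pct = cd,
       synaptic_only_pct = if (is.null(so)) data.frame() else so)
}
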