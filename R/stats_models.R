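#' Gaussian fits to per-group count histograms with extra sum-of-squares F
#' test
#'
#' Per-spine cluster counts, grouped (e.g. by the number of scaffold
#' nanomodules in the spine), are binned at integer centers (bin width 1)
#' and each group's histogram is fitted with a Gaussian (amplitude, mean,
#' SD). The null model shares one mean and SD across groups (amplitudes
#' stay free); the F statistic is
#' `F = ((RSS_shared - RSS_sep) / ddf) / (RSS_sep / df_sep)` with
#' `ddf = 2 (G - 1)`, and p comes from the F distribution. Counts are
#' discrete; fitting their binned histograms with continuous Gaussians is
#' a faithfulness choice, with probability-normalized histograms available
#' via `normalize`.
#'
#' The default `"gaussian"` method mirrors the field-standard curve-fit
#' comparison exactly; because histogram bin counts carry multinomial
#' (heteroscedastic) noise rather than iid Gaussian noise, its F test is
#' anticonservative on count data (its p-values are exact only under
#' Gaussian bin noise). The `"multinomial"` method replaces the F test
#' with a likelihood-ratio test of shared vs per-group discretized
#' Gaussians under the exact multinomial likelihood, which is calibrated
#' for counts; the Gaussian parameters it reports are maximum-likelihood
#' rather than least-squares.
#'
#' @param counts integer vector of per-spine counts.
#' @param group grouping factor (>= 2 levels, each with >= 5 spines).
#' @param normalize fit probability-normalized histograms instead of
#'   frequencies (gaussian method only).
#' @param method `"gaussian"` (least-squares curve fits, extra
#'   sum-of-squares F test) or `"multinomial"` (exact count likelihood,
#'   LRT with chi-square p).
#' @return list of class `count_dist_fit`: `fits` (per-group parameters),
#'   `shared` (shared-model parameters), `rss_separate`, `rss_shared`,
#'   `F`, `df`, `p`, `degenerate`, `method`.
#' @export
fit_count_distributions <- function(counts, group, normalize = FALSE,
                                    method = c("gaussian", "multinomial")) {
  method <- match.arg(method)
  if (method == "multinomial") {
    return(fit_count_multinomial(counts, group))
  }
  group <- droplevels(as.factor(group))
  G <- nlevels(group)
  if (G < 2) stop("need >= 2 groups")
  if (any(table(group) < 5)) stop("each group needs >= 5 spines")
  degenerate <- any(tapply(counts, group, function(x) length(unique(x)) == 1))
  bins <- seq(min(counts), max(counts))
  H <- lapply(levels(group), function(g) {
    h <- tabulate(counts[group == g] - min(counts) + 1L, length(bins))
    if (normalize) h <- h / sum(h)
    h
  })
  names(H) <- levels(group)
  x <- bins
  gfun <- function(a, m, s) a * exp(-(x - m)^2 / (2 * s^2))
  mstart <- vapply(H, function(h) sum(x * h) / sum(h), numeric(1))
  sstart <- vapply(seq_along(H), function(i) {
    max(0.5, sqrt(sum(H[[i]] * (x - mstart[i])^2) / sum(H[[i]])))
  }, numeric(1))
  astart <- vapply(H, max, numeric(1))
  fit1 <- function(h, a0, m0, s0) {
    f <- tryCatch(
      minpack.lm::nls.lm(
        par = list(a = a0, m = m0, s = s0),
        fn = function(p) h - gfun(p$a, p$m, abs(p$s)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(f)) return(NULL)
    list(a = f$par$a, m = f$par$m, s = abs(f$par$s), rss = sum(f$fvec^2))
  }
  seps <- lapply(seq_along(H), function(i) {
    fit1(H[[i]], astart[i], mstart[i], sstart[i])
  })
  if (any(vapply(seps, is.null, logical(1)))) degenerate <- TRUE
  rss_sep <- sum(vapply(seps, function(f) if (is.null(f)) NA_real_ else f$rss,
                        numeric(1)))
  # shared mean/SD, free amplitudes
  shared <- tryCatch(
    minpack.lm::nls.lm(
      par = c(list(m = mean(mstart), s = max(0.5, mean(sstart))),
              stats::setNames(as.list(astart), paste0("a", seq_len(G)))),
      fn = function(p) {
        unlist(lapply(seq_len(G), function(i) {
          H[[i]] - gfun(p[[paste0("a", i)]], p$m, abs(p$s))
        }))
      },
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(shared)) degenerate <- TRUE
  rss_sh <- if (is.null(shared)) NA_real_ else sum(shared$fvec^2)
  # nested models: the shared fit can never beat the separate fits
  if (!is.na(rss_sh) && !is.na(rss_sep)) rss_sh <- max(rss_sh, rss_sep)
  n_obs <- G * length(bins)
  df_sep <- n_obs - 3 * G
  ddf <- 2 * (G - 1)
  Fst <- if (degenerate || df_sep <= 0) {
    NA_real_
  } else {
    ((rss_sh - rss_sep) / ddf) / (rss_sep / df_sep)
  }
  p <- if (is.na(Fst)) NA_real_ else stats::pf(Fst, ddf, df_sep,
                                               lower.tail = FALSE)
  structure(
    list(
      fits = lapply(seps, function(f) f[c("a", "m", "s")]),
      shared = if (is.null(shared)) NULL else {
        list(m = shared$par$m, s = abs(shared$par$s),
             a = unlist(shared$par[paste0("a", seq_len(G))]))
      },
      bins = bins, histograms = H,
      rss_separate = rss_sep, rss_shared = rss_sh,
      F = Fst, df = c(ddf, df_sep), p = p, degenerate = degenerate,
      method = "gaussian"
    ),
    class = "count_dist_fit"
  )
}

# exact-likelihood alternative: discretized-Gaussian class probabilities,
# shared vs per-group (m, s), LRT with 2(G-1) df
fit_count_multinomial <- function(counts, group) {
  group <- droplevels(as.factor(group))
  G <- nlevels(group)
  if (G < 2) stop("need >= 2 groups")
  if (any(table(group) < 5)) stop("each group needs >= 5 spines")
  degenerate <- any(tapply(counts, group, function(x) length(unique(x)) == 1))
  bins <- seq(min(counts), max(counts))
  H <- lapply(levels(group), function(g) {
    tabulate(counts[group == g] - min(counts) + 1L, length(bins))
  })
  names(H) <- levels(group)
  nll <- function(par, h) {
    m <- par[1]; s <- exp(par[2])
    lp <- -(bins - m)^2 / (2 * s^2)
    lp <- lp - log(sum(exp(lp)))
    -sum(h * lp)
  }
  fit1 <- function(h) {
    mu <- sum(bins * h) / sum(h)
    sd0 <- sqrt(sum(h * (bins - mu)^2) / sum(h)) + 0.3
    o <- stats::optim(c(mu, log(sd0)), nll, h = h)
    list(m = o$par[1], s = exp(o$par[2]), nll = o$value)
  }
  seps <- lapply(H, fit1)
  shared <- fit1(Reduce(`+`, H))
  lrt <- max(0, 2 * (shared$nll - sum(vapply(seps, `[[`, numeric(1), "nll"))))
  ddf <- 2 * (G - 1)
  p <- if (degenerate) NA_real_ else {
    stats::pchisq(lrt, df = ddf, lower.tail = FALSE)
  }
  structure(
    list(
      fits = lapply(seps, function(f) list(a = NA_real_, m = f$m, s = f$s)),
      shared = list(m = shared$m, s = shared$s, a = NA_real_),
      bins = bins, histograms = H,
      rss_separate = NA_real_, rss_shared = NA_real_,
      F = NA_real_, lrt = lrt, df = c(ddf, NA_real_), p = p,
      degenerate = degenerate, method = "multinomial"
    ),
    class = "count_dist_fit"
  )
}

#' Linear scaling of cluster count with spine head area
#'
#' Ordinary least squares of count on area: slope (clusters per um^2) with
#' SE, intercept, R^2, Pearson r and its two-tailed p.
#'
#' @param head_areas spine head areas (um^2).
#' @param cluster_counts matching per-spine cluster counts.
#' @return list of class `scaling_fit`: `slope`, `slope_se`, `intercept`,
#'   `r_squared`, `pearson_r`, `p`, `n`.
#' @export
scaling_regression <- function(head_areas, cluster_counts) {
  stopifnot(length(head_areas) == length(cluster_counts))
  n <- length(head_areas)
  if (n < 3) stop("need n >= 3")
  if (stats::var(head_areas) == 0) stop("zero area variance")
  fit <- stats::lm(cluster_counts ~ head_areas)
  s <- summary(fit)
  ct <- stats::cor.test(head_areas, cluster_counts)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      slope_se = s$coefficients[2, 2],
      intercept = unname(stats::coef(fit)[1]),
      r_squared = s$r.squared,
      pearson_r = unname(ct$estimate),
      p = ct$p.value,
      n = n
    ),
    class = "scaling_fit"
  )
}

#' One-way ANCOVA: homogeneity of count-vs-area slopes across groups
#'
#' Tests whether the scaling slope differs between groups via the
#' area-by-group interaction term of `count ~ area * group`; returns the
#' interaction F and p plus per-group slopes.
#'
#' @param area,count paired observations.
#' @param group grouping factor (>= 2 levels, each n >= 3).
#' @return list of class `ancova_fit`: `slopes` (per group), `F`, `df`,
#'   `p`.
#' @export
ancova_slopes <- function(area, count, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) < 3)) stop("each group needs n >= 3")
  v <- tapply(area, group, stats::var)
  if (any(v == 0)) stop("a group has zero area variance")
  fit <- stats::lm(count ~ area * group)
  an <- stats::anova(fit)
  irow <- grep(":", rownames(an))
  slopes <- vapply(levels(group), function(g) {
    unname(stats::coef(stats::lm(count[group == g] ~ area[group == g]))[2])
  }, numeric(1))
  structure(
    list(
      slopes = slopes,
      F = an$`F value`[irow],
      df = c(an$Df[irow], an$Df[nrow(an)]),
      p = an$`Pr(>F)`[irow]
    ),
    class = "ancova_fit"
  )
}

#' Two-sample two-tailed Kolmogorov-Smirnov comparison
#'
#' @param sample_a,sample_b numeric samples (each n >= 2).
#' @param method `"asymptotic"` (default) or `"exact"` (available for
#'   samples up to 25).
#' @return list `D`, `p`, `n`.
#' @export
ks_compare <- function(sample_a, sample_b, method = "asymptotic") {
  if (length(sample_a) < 2 || length(sample_b) < 2) stop("empty sample")
  exact <- method == "exact" && length(sample_a) <= 25 && length(sample_b) <= 25
  kt <- suppressWarnings(
    stats::ks.test(sample_a, sample_b, exact = exact)
  )
  list(D = unname(kt$statistic), p = kt$p.value,
       n = c(length(sample_a), length(sample_b)))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param values numeric observations.
#' @param group grouping factor (>= 3 levels, each n >= 2).
#' @return list `F`, `p`, `tukey` (data.frame: comparison, diff,
#'   adjusted p).
#' @export
anova_tukey <- function(values, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 3) stop("need >= 3 groups")
  if (any(table(group) < 2)) stop("a group has n < 2")
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(
    F = an$`F value`[1],
    p = an$`Pr(>F)`[1],
    tukey = data.frame(
      comparison = rownames(tk),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"],
      row.names = NULL
    )
  )
}

#' Multivariable linear regression of spine size on two cluster counts
#'
#' `area ~ nA + nB` by least squares, with per-coefficient SEs and partial
#' F tests. Collinear or constant predictors are flagged rather than
#' silently fitted.
#'
#' @param head_areas spine head areas (um^2).
#' @param n_a,n_b per-spine counts of the two cluster types.
#' @return list of class `multivar_fit`: `coefficients` (data.frame with
#'   estimate, se, partial F, p), `intercept`, `r_squared`, `n`,
#'   `collinear`.
#' @export
multivar_size_regression <- function(head_areas, n_a, n_b) {
  n <- length(head_areas)
  stopifnot(length(n_a) == n, length(n_b) == n)
  if (n < 10) stop("need n >= 10 spines")
  collinear <- FALSE
  if (stats::var(n_a) == 0 || stats::var(n_b) == 0) {
    collinear <- TRUE
  } else if (abs(stats::cor(n_a, n_b)) > 0.99) {
    collinear <- TRUE
  }
  if (collinear) {
    return(structure(
      list(coefficients = NULL, intercept = NA_real_, r_squared = NA_real_,
           n = n, collinear = TRUE),
      class = "multivar_fit"
    ))
  }
  fit <- stats::lm(head_areas ~ n_a + n_b)
  s <- summary(fit)
  dr <- stats::drop1(fit, test = "F")
  co <- data.frame(
    term = c("n_a", "n_b"),
    estimate = unname(stats::coef(fit)[c("n_a", "n_b")]),
    se = s$coefficients[c("n_a", "n_b"), 2],
    F = dr[c("n_a", "n_b"), "F value"],
    p = dr[c("n_a", "n_b"), "Pr(>F)"],
    row.names = NULL
  )
  structure(
    list(
      coefficients = co,
      intercept = unname(stats::coef(fit)[1]),
      intercept_se = s$coefficients[1, 2],
      r_squared = s$r.squared,
      n = n, collinear = FALSE
    ),
    class = "multivar_fit"
  )
}

#' Classify time-lapse spines as potentiated or non-responsive
#'
#' A spine is potentiated iff its area exceeds baseline * (1 + threshold)
#' immediately after the stimulus AND stays enlarged for the whole
#' post-stimulus series, operationalized as every trailing 3-frame running
#' mean of the post series staying above the same bound. Records missing
#' baseline or post frames are skipped with a message.
#'
#' @param records long data.frame from [simulate_timelapse()] (or with the
#'   same columns: `spine_id`, `frame`, `phase`, `area_um2`).
#' @param threshold relative increase defining potentiation (default 0.10).
#' @param run_frames running-mean window (default 3).
#' @return data.frame `spine_id`, `class` (`potentiated` /
#'   `non_responsive`), `baseline_area_um2`.
#' @export
classify_potentiated <- function(records, threshold = 0.10, run_frames = 3L) {
  out <- lapply(split(records, records$spine_id), function(d) {
    d <- d[order(d$frame), ]
    base <- d$area_um2[d$phase == "baseline"]
    post <- d$area_um2[d$phase == "post"]
    if (length(base) < 2 || length(post) < 2) {
      message(sprintf("spine %s skipped: missing frames", d$spine_id[1]))
      return(NULL)
    }
    bound <- mean(base) * (1 + threshold)
    w <- min(run_frames, length(post))
    run <- stats::filter(post, rep(1 / w, w), sides = 1)
    run <- run[!is.na(run)]
    pot <- post[1] >= bound && all(run >= bound)
    data.frame(
      spine_id = d$spine_id[1],
      class = if (pot) "potentiated" else "non_responsive",
      baseline_area_um2 = mean(base)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
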