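# Anna-Karenina trajectory analysis: beta-diversity between vessel pairs
# over time and within vessels across time lags, with permutation slope
# tests and cluster-bootstrap confidence intervals.

PAIR_CATEGORIES <- c("treatment-treatment", "control-control",
                     "treatment-control", "within-vessel")

# Align metadata rows to a vector of sample ids.
align_metadata <- function(md, ids) {
  m <- match(ids, md$sample_id)
  if (anyNA(m))
    stop("metadata missing samples: ",
         paste(utils::head(ids[is.na(m)], 5L), collapse = ", "),
         call. = FALSE)
  md[m, , drop = FALSE]
}

# Build the point set for one pair category from a precomputed distance
# matrix and aligned metadata.
series_from_dist <- function(d, md, pair_category) {
  ids <- rownames(d)
  md <- align_metadata(md, ids)
  pts <- NULL
  if (pair_category == "within-vessel") {
    for (v in unique(md$vessel)) {
      idx <- which(md$vessel == v)
      if (length(idx) < 2L) next
      cmb <- utils::combn(idx, 2L)
      pts <- rbind(pts, data.frame(
        time_h = abs(md$time_h[cmb[1, ]] - md$time_h[cmb[2, ]]),
        dissimilarity = d[cbind(cmb[1, ], cmb[2, ])],
        vessel_a = v, vessel_b = v, pair_id = v,
        stringsAsFactors = FALSE))
    }
  } else {
    want <- switch(pair_category,
      "treatment-treatment" = c("treatment", "treatment"),
      "control-control" = c("control", "control"),
      "treatment-control" = c("treatment", "control"))
    vs <- unique(md[, c("vessel", "condition")])
    va <- vs$vessel[vs$condition == want[1]]
    vb <- vs$vessel[vs$condition == want[2]]
    pairs <- if (want[1] == want[2]) {
      if (length(va) < 2L) list() else
        utils::combn(va, 2L, simplify = FALSE)
    } else {
      unlist(lapply(va, function(a) lapply(vb, function(b) c(a, b))),
             recursive = FALSE)
    }
    for (p in pairs) {
      ia <- which(md$vessel == p[1])
      ib <- which(md$vessel == p[2])
      shared <- intersect(md$time_h[ia], md$time_h[ib])
      for (t in shared) {
        i <- ia[md$time_h[ia] == t]
        j <- ib[md$time_h[ib] == t]
        pts <- rbind(pts, data.frame(
          time_h = t, dissimilarity = d[i, j],
          vessel_a = p[1], vessel_b = p[2],
          pair_id = paste(p[1], p[2], sep = "|"),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(pts) || nrow(pts) == 0L)
    stop("no qualifying pairs for category '", pair_category, "'",
         call. = FALSE)
  structure(pts, class = c("pair_series", "data.frame"),
            pair_category = pair_category)
}

#' Build a beta-diversity pair series
#'
#' Enumerates the dissimilarity points of one pair category:
#' between-vessel categories (`treatment-treatment`, `control-control`,
#' `treatment-control`) pair distinct vessels at identical nominal time
#' points; `within-vessel` pairs samples of the same vessel at distinct
#' times and records the time lag `|t_a - t_b|`.
#'
#' @param x A [community_table()].
#' @param metadata A [sample_metadata()] covering all samples of `x`.
#' @param metric Dissimilarity metric passed to [pairwise_distances()].
#' @param tax,rank Optional taxonomy and rank for aggregation.
#' @param pair_category One of `"treatment-treatment"`,
#'   `"control-control"`, `"treatment-control"`, `"within-vessel"`.
#' @return A `pair_series` data.frame with columns `time_h` (time, or lag
#'   for within-vessel), `dissimilarity`, `vessel_a`, `vessel_b`,
#'   `pair_id`.
#' @export
build_pair_series <- function(x, metadata,
                              metric = c("bray_curtis", "jaccard",
                                         "theta_yc"),
                              tax = NULL, rank = NULL,
                              pair_category = PAIR_CATEGORIES) {
  metric <- match.arg(metric)
  pair_category <- match.arg(pair_category, PAIR_CATEGORIES)
  d <- pairwise_distances(x, metric, tax = tax, rank = rank)
  series_from_dist(d, metadata, pair_category)
}

slope_only <- function(t, y) {
  stats::cov(t, y) / stats::var(t)
}

#' Ordinary least-squares slope of dissimilarity on time
#'
#' @param series A `pair_series` (or any data.frame with `time_h` and
#'   `dissimilarity`), at least 3 points over at least 2 distinct times.
#' @return List with `slope` (dissimilarity per hour) and `intercept`.
#' @export
fit_slope <- function(series) {
  if (nrow(series) < 3L)
    stop("need at least 3 points", call. = FALSE)
  if (length(unique(series$time_h)) < 2L)
    stop("all times equal; slope undefined", call. = FALSE)
  co <- stats::coef(stats::lm(dissimilarity ~ time_h, data = series))
  list(slope = unname(co[2L]), intercept = unname(co[1L]))
}

#' Permutation test for a non-zero trajectory slope
#'
#' The null distribution is generated by permuting time labels within
#' each vessel pair's sub-series, preserving the grouping of points that
#' share a vessel pair while destroying any time trend. Two-sided by
#' `|slope|`, add-one convention.
#'
#' @param series A `pair_series`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @return The permutation p-value.
#' @export
permutation_slope_test <- function(series, n_perm = 1000L, seed = NULL) {
  if (nrow(series) < 3L) stop("need at least 3 points", call. = FALSE)
  # canonical point order makes the result invariant to row shuffles
  series <- series[order(series$pair_id, series$time_h,
                         series$dissimilarity), ]
  t <- series$time_h
  y <- series$dissimilarity
  if (length(unique(t)) < 2L)
    stop("all times equal; slope undefined", call. = FALSE)
  obs <- abs(slope_only(t, y))
  idx_by_pair <- split(seq_along(t), series$pair_id)
  .with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      tp <- t
      for (idx in idx_by_pair)
        tp[idx] <- t[idx][sample.int(length(idx))]
      if (abs(slope_only(tp, y)) >= obs - 1e-15) exceed <- exceed + 1L
    }
    (exceed + 1) / (n_perm + 1)
  })
}

#' Cluster-bootstrap confidence interval for a trajectory slope
#'
#' Resamples vessel pairs (`pair_id`) with replacement -- points within a
#' pair are dependent, so the pair is the resampling unit -- refits the
#' OLS slope on each resample, and returns the 2.5/97.5 percentile
#' interval.
#'
#' @param series A `pair_series` with at least 2 distinct `pair_id`s.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional seed.
#' @return Numeric vector `c(lo, hi)`.
#' @export
bootstrap_slope_ci <- function(series, n_boot = 1000L, seed = NULL) {
  pids <- unique(series$pair_id)
  if (length(pids) < 2L)
    stop("need at least 2 distinct pair_ids for the cluster bootstrap",
         call. = FALSE)
  series <- series[order(series$pair_id, series$time_h,
                         series$dissimilarity), ]
  idx_by_pair <- split(seq_len(nrow(series)), series$pair_id)
  t <- series$time_h
  y <- series$dissimilarity
  .with_seed(seed, {
    slopes <- vapply(seq_len(n_boot), function(b) {
      take <- unlist(idx_by_pair[sample(length(pids), replace = TRUE)],
                     use.names = FALSE)
      if (stats::var(t[take]) == 0) return(NA_real_)
      slope_only(t[take], y[take])
    }, 0)
    lo_hi <- stats::quantile(slopes, c(0.025, 0.975), na.rm = TRUE,
                             names = FALSE)
    c(lo = lo_hi[1], hi = lo_hi[2])
  })
}

#' Slope inference across taxonomic ranks and pair categories
#'
#' Runs the full grid of (rank x pair category) trajectory analyses:
#' point estimate, cluster-bootstrap 95% CI and permutation p-value for
#' each series. Child seeds are derived deterministically from `seed` so
#' the grid is reproducible and individual cells can be rerun in
#' isolation.
#'
#' @inheritParams build_pair_series
#' @param ranks Subset of genus, family, order, class, phylum.
#' @param categories Pair categories to analyse.
#' @param n_perm,n_boot Permutation and bootstrap replicates.
#' @param seed Optional base seed.
#' @return data.frame with one row per (rank, pair_category): `slope`,
#'   `intercept`, `ci_lo`, `ci_hi`, `p_value`, `n_points`,
#'   `n_permutations`, `n_bootstrap`.
#' @export
multi_rank_akh <- function(x, tax, metadata,
                           metric = c("bray_curtis", "jaccard", "theta_yc"),
                           ranks = c("genus", "family", "order", "class",
                                     "phylum"),
                           categories = PAIR_CATEGORIES,
                           n_perm = 1000L, n_boot = 1000L, seed = NULL) {
  metric <- match.arg(metric)
  bad <- setdiff(ranks, setdiff(TAX_RANKS, "kingdom"))
  if (length(bad))
    stop("unsupported ranks: ", paste(bad, collapse = ", "), call. = FALSE)
  out <- NULL
  cell <- 0L
  for (rk in ranks) {
    d <- pairwise_distances(x, metric, tax = tax, rank = rk)
    for (cat in categories) {
      cell <- cell + 1L
      s <- series_from_dist(d, metadata, cat)
      fit <- fit_slope(s)
      sd1 <- if (is.null(seed)) NULL else derive_seed(seed, 2L * cell)
      sd2 <- if (is.null(seed)) NULL else derive_seed(seed, 2L * cell + 1L)
      p <- permutation_slope_test(s, n_perm = n_perm, seed = sd1)
      ci <- bootstrap_slope_ci(s, n_boot = n_boot, seed = sd2)
      out <- rbind(out, data.frame(
        rank = rk, pair_category = cat, metric = metric,
        n_points = nrow(s), slope = fit$slope, intercept = fit$intercept,
        ci_lo = ci[["lo"]], ci_hi = ci[["hi"]], p_value = p,
        n_permutations = as.integer(n_perm),
        n_bootstrap = as.integer(n_boot),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Estimate the time of peak between-vessel dispersion
#'
#' Averages dissimilarity per time point, smooths with a moving average
#' over one feeding cycle (24 h window), and returns the time of the
#' smoothed maximum. Ties are broken to the earliest time.
#'
#' @param series A between-vessel `pair_series` with at least 4 distinct
#'   times.
#' @param window Smoothing window in hours (default 24, one feeding
#'   cycle).
#' @return Estimated peak time in hours.
#' @export
dispersion_peak_estimate <- function(series, window = 24) {
  times <- sort(unique(series$time_h))
  if (length(times) < 4L)
    stop("need at least 4 distinct times", call. = FALSE)
  mu <- vapply(times, function(t)
    mean(series$dissimilarity[series$time_h == t]), 0)
  sm <- vapply(times, function(t)
    mean(mu[abs(times - t) <= window / 2]), 0)
  times[which.max(sm)]  # which.max takes the first (earliest) maximum
}
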