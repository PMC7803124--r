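# Distance-matrix inference: AMOVA, HOMOVA, principal coordinate analysis.

# Resolve a grouping vector against the ids of a distance matrix.
resolve_groups <- function(d, groups) {
  ids <- rownames(d)
  if (!is.null(names(groups))) {
    miss <- setdiff(ids, names(groups))
    if (length(miss))
      stop("ungrouped sample ids: ", paste(utils::head(miss, 5L),
                                           collapse = ", "), call. = FALSE)
    groups <- groups[ids]
  } else if (length(groups) != nrow(d)) {
    stop("`groups` must be named by sample id or match the matrix order",
         call. = FALSE)
  }
  g <- as.factor(as.vector(groups))
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("every group needs at least 2 members", call. = FALSE)
  g
}

# Sums of squares from a squared-distance matrix for one labelling.
amova_ss <- function(d2, g) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

amova_f <- function(d2, g) {
  ss <- amova_ss(d2, g)
  k <- nlevels(g)
  n <- nrow(d2)
  (ss["among"] / (k - 1)) / (ss["within"] / (n - k))
}

# All distinct assignments of the multiset of group labels to samples,
# as a list of factor vectors (levels preserved). Count must stay small.
enumerate_groupings <- function(g, limit = 2e5) {
  sizes <- table(g)
  total <- exp(lgamma(length(g) + 1) - sum(lgamma(sizes + 1)))
  if (total > limit)
    stop("too many distinct relabellings for exhaustive enumeration",
         call. = FALSE)
  levs <- levels(g)
  rec <- function(free, si) {
    if (si == length(levs))
      return(list(stats::setNames(rep(levs[si], length(free)), free)))
    out <- list()
    picks <- utils::combn(free, sizes[si], simplify = FALSE)
    for (p in picks) {
      rest <- setdiff(free, p)
      for (tail in rec(rest, si + 1L))
        out[[length(out) + 1L]] <- c(stats::setNames(rep(levs[si],
                                                         length(p)), p), tail)
    }
    out
  }
  asg <- rec(seq_along(g), 1L)
  lapply(asg, function(a) factor(a[as.character(seq_along(g))],
                                 levels = levs))
}

#' Analysis of molecular variance (AMOVA)
#'
#' Partitions squared pairwise dissimilarities into among- and
#' within-group components and tests the among-group component by random
#' relabelling of group membership:
#' \eqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' \eqn{F = \frac{SS_{among}/(k-1)}{SS_{within}/(N-k)}}. The permutation
#' p-value uses the add-one convention, so it is never zero.
#'
#' @param d Symmetric distance matrix with sample ids as dimnames.
#' @param groups Group labels, either named by sample id or ordered as the
#'   matrix; at least two groups of at least two samples.
#' @param n_perm Number of random relabellings (default 1000).
#' @param seed Optional seed for the permutation stream.
#' @param exhaustive If TRUE, enumerate every distinct relabelling instead
#'   of sampling; the p-value is then the exact permutation p (observed
#'   labelling included, no add-one term).
#' @return Object of class `amova_result`: list with `ss_among`,
#'   `ss_within`, `ss_total`, `df_among`, `df_within`, `f_stat`,
#'   `p_value`, `n_permutations`.
#' @export
amova <- function(d, groups, n_perm = 1000L, seed = NULL,
                  exhaustive = FALSE) {
  check_dist_matrix(d, range01 = FALSE)
  g <- resolve_groups(d, groups)
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  d2 <- d^2
  ss <- amova_ss(d2, g)
  k <- nlevels(g)
  n <- nrow(d)
  f_obs <- unname((ss["among"] / (k - 1)) / (ss["within"] / (n - k)))
  if (exhaustive) {
    all_g <- enumerate_groupings(g)
    fs <- vapply(all_g, function(gi) amova_f(d2, gi), 0)
    p <- mean(fs >= f_obs - 1e-12)
    n_used <- length(all_g)
  } else {
    exceed <- .with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(b) {
        amova_f(d2, g[sample.int(n)]) >= f_obs - 1e-12
      }, NA))
    })
    p <- (exceed + 1) / (n_perm + 1)
    n_used <- as.integer(n_perm)
  }
  structure(list(ss_among = unname(ss["among"]),
                 ss_within = unname(ss["within"]),
                 ss_total = unname(ss["total"]),
                 df_among = k - 1L, df_within = n - k,
                 f_stat = f_obs,
                 p_value = p,
                 n_permutations = n_used),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf(
    "AMOVA: SS_among %.4g (df %d), SS_within %.4g (df %d), F = %.4g, p = %.4g (%d permutations)\n",
    x$ss_among, x$df_among, x$ss_within, x$df_within, x$f_stat, x$p_value,
    x$n_permutations))
  invisible(x)
}

homova_b <- function(d2, g) {
  n <- nrow(d2)
  k <- nlevels(g)
  s2 <- vapply(levels(g), function(lev) {
    idx <- which(g == lev)
    ng <- length(idx)
    (sum(d2[idx, idx]) / (2 * ng)) / (ng - 1)
  }, 0)
  s2 <- pmax(s2, .Machine$double.xmin)  # guard log(0) on degenerate groups
  ngs <- tabulate(g)
  pooled <- sum(s2 * (ngs - 1)) / (n - k)
  (n - k) * log(pooled) - sum((ngs - 1) * log(s2))
}

#' Homogeneity of molecular variance (HOMOVA)
#'
#' Bartlett-style test of equal within-group dispersion on a distance
#' matrix. Group variances are \eqn{s_g^2 = SSw_g / (n_g - 1)} with
#' \eqn{SSw_g = \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2}; the statistic is
#' \eqn{B = (N-k)\ln s_p^2 - \sum_g (n_g-1) \ln s_g^2} and the p-value
#' comes from random relabelling (one-sided, add-one convention).
#'
#' @inheritParams amova
#' @return Object of class `homova_result`: list with `b_stat`,
#'   `p_value`, `n_permutations`, `group_variances`.
#' @export
homova <- function(d, groups, n_perm = 1000L, seed = NULL,
                   exhaustive = FALSE) {
  check_dist_matrix(d, range01 = FALSE)
  g <- resolve_groups(d, groups)
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  d2 <- d^2
  b_obs <- homova_b(d2, g)
  n <- nrow(d)
  if (exhaustive) {
    all_g <- enumerate_groupings(g)
    bs <- vapply(all_g, function(gi) homova_b(d2, gi), 0)
    s2 <- vapply(levels(g), function(lev) {
      idx <- which(g == lev)
      (sum(d2[idx, idx]) / (2 * length(idx))) / (length(idx) - 1)
    }, 0)
    return(structure(list(b_stat = b_obs,
                          p_value = mean(bs >= b_obs - 1e-12),
                          n_permutations = length(all_g),
                          group_variances = s2),
                     class = "homova_result"))
  }
  exceed <- .with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      homova_b(d2, g[sample.int(n)]) >= b_obs - 1e-12
    }, NA))
  })
  s2 <- vapply(levels(g), function(lev) {
    idx <- which(g == lev)
    (sum(d2[idx, idx]) / (2 * length(idx))) / (length(idx) - 1)
  }, 0)
  structure(list(b_stat = b_obs,
                 p_value = (exceed + 1) / (n_perm + 1),
                 n_permutations = as.integer(n_perm),
                 group_variances = s2),
            class = "homova_result")
}

#' @export
print.homova_result <- function(x, ...) {
  cat(sprintf("HOMOVA: B = %.4g, p = %.4g (%d permutations)\n",
              x$b_stat, x$p_value, x$n_permutations))
  invisible(x)
}

#' Principal coordinate analysis
#'
#' Metric embedding of a distance matrix: Gower double-centering of
#' \eqn{-\frac{1}{2} d_{ij}^2} followed by eigendecomposition. Axes are
#' ordered by eigenvalue. Negative eigenvalues (non-Euclidean matrices
#' such as Bray-Curtis or Yue-Clayton) are reported but excluded from the
#' variance fractions; no Lingoes/Cailliez correction is applied.
#'
#' @param d Symmetric distance matrix with ids as dimnames, n >= 2.
#' @return Object of class `pcoa_result`: `coordinates` (samples x
#'   positive axes), `eigenvalues` (all, descending), `pct_variance`
#'   (percent per positive axis, summing to 100).
#' @export
pcoa <- function(d) {
  check_dist_matrix(d, range01 = FALSE)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  a <- -0.5 * d^2
  g <- a - matrix(rowMeans(a), n, n) -
    matrix(colMeans(a), n, n, byrow = TRUE) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  dimnames(coords) <- list(rownames(d), paste0("Axis", seq_along(pos)))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 pct_variance = 100 * e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(2L, ncol(x$coordinates))
  cat(sprintf("PCoA: %d samples, %d positive axes; first %d axes explain %.1f%% of variance\n",
              nrow(x$coordinates), ncol(x$coordinates), k,
              sum(x$pct_variance[seq_len(k)])))
  invisible(x)
}
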