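# Pairwise community dissimilarities: Bray-Curtis, Jaccard, Yue-Clayton.

check_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have the same length", call. = FALSE)
  if (!is.numeric(x) || !is.numeric(y) || any(x < 0) || any(y < 0))
    stop("abundances must be nonnegative", call. = FALSE)
  if (sum(x) == 0 || sum(y) == 0)
    stop("each sample must contain at least one read", call. = FALSE)
  invisible(NULL)
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{d = \sum_k |x_k - y_k| / \sum_k (x_k + y_k)}. By default both
#' samples are first converted to relative abundances, removing
#' library-size artifacts; set `proportions = FALSE` for the raw-counts
#' form (sensitivity checks only).
#'
#' @param x,y Nonnegative abundance vectors of equal length, neither
#'   all-zero.
#' @param proportions Normalise each sample to sum 1 first (default TRUE).
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y, proportions = TRUE) {
  check_pair(x, y)
  if (proportions) {
    x <- x / sum(x)
    y <- y / sum(y)
  }
  sum(abs(x - y)) / sum(x + y)
}

#' Jaccard dissimilarity
#'
#' \eqn{1 - |A \cap B| / |A \cup B|} on the presence sets; reflects
#' membership only, never relative abundance.
#'
#' @inheritParams bray_curtis
#' @return Dissimilarity in `[0, 1]`.
#' @export
jaccard <- function(x, y) {
  check_pair(x, y)
  a <- x > 0
  b <- y > 0
  1 - sum(a & b) / sum(a | b)
}

#' Yue-Clayton dissimilarity (1 - theta_YC)
#'
#' On relative abundances \eqn{a_i, b_i}:
#' \eqn{d = 1 - \sum a_i b_i / (\sum (a_i - b_i)^2 + \sum a_i b_i)}.
#' Reported as a distance (one minus the Yue-Clayton similarity), the
#' mothur convention.
#'
#' @inheritParams bray_curtis
#' @return Dissimilarity in `[0, 1]`.
#' @export
theta_yc <- function(x, y) {
  check_pair(x, y)
  a <- x / sum(x)
  b <- y / sum(y)
  cross <- sum(a * b)
  1 - cross / (sum((a - b)^2) + cross)
}

BETA_METRICS <- c("bray_curtis", "jaccard", "theta_yc")

#' Pairwise distance matrix for a community table
#'
#' Optionally aggregates to a taxonomic rank first, then fills a symmetric
#' matrix of pairwise dissimilarities under the chosen metric.
#' Abundance-based metrics are computed on per-sample relative abundances
#' (see [bray_curtis()]).
#'
#' @param x A [community_table()].
#' @param metric One of `"bray_curtis"`, `"jaccard"`, `"theta_yc"`.
#' @param tax Optional [taxonomy_map()]; required when `rank` is given.
#' @param rank Optional taxonomic rank to aggregate to before computing
#'   distances.
#' @param proportions Normalise rows to relative abundance (abundance
#'   metrics only).
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
pairwise_distances <- function(x, metric = c("bray_curtis", "jaccard",
                                             "theta_yc"),
                               tax = NULL, rank = NULL, proportions = TRUE) {
  metric <- match.arg(metric)
  if (!is.null(rank)) {
    if (is.null(tax))
      stop("`tax` is required when `rank` is given", call. = FALSE)
    x <- aggregate_to_rank(x, tax, rank)
  }
  m <- x$counts
  d <- switch(metric,
    bray_curtis = {
      p <- if (proportions) m / rowSums(m) else m
      man <- as.matrix(stats::dist(p, method = "manhattan"))
      man / outer(rowSums(p), rowSums(p), `+`)
    },
    jaccard = {
      b <- (m > 0) * 1
      inter <- tcrossprod(b)
      union <- outer(diag(inter), diag(inter), `+`) - inter
      1 - inter / union
    },
    theta_yc = {
      p <- m / rowSums(m)
      cross <- tcrossprod(p)
      sq <- rowSums(p^2)
      1 - cross / (outer(sq, sq, `+`) - cross)
    })
  diag(d) <- 0
  d <- (d + t(d)) / 2  # enforce exact symmetry against rounding
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}
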