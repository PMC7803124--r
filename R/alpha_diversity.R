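# Within-sample (alpha) diversity indices and rarefaction curves.

check_counts <- function(counts) {
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0))
    stop("counts must be a nonnegative numeric vector", call. = FALSE)
  if (sum(counts) <= 0)
    stop("counts must contain at least one read", call. = FALSE)
  invisible(counts)
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over taxa with positive counts, with
#' \eqn{p_i = x_i / N}. Natural logarithm (mothur convention); values in
#' other log bases differ by a constant factor.
#'
#' @param counts Nonnegative numeric vector of taxon counts, sum > 0.
#' @return Shannon index (nats).
#' @examples
#' shannon(c(5, 5, 5, 5))  # log(4)
#' @export
shannon <- function(counts) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Inverse Simpson diversity index
#'
#' \eqn{D = 1 / \sum_i p_i^2}; equals the number of taxa for a perfectly
#' even community.
#'
#' @inheritParams shannon
#' @return Inverse Simpson index, in `[1, S_obs]`.
#' @export
inv_simpson <- function(counts) {
  check_counts(counts)
  p <- counts / sum(counts)
  1 / sum(p^2)
}

#' Chao1 richness estimator (bias-corrected)
#'
#' \eqn{S_{chao1} = S_{obs} + n_1 (n_1 - 1) / (2 (n_2 + 1))} where
#' \eqn{n_1} and \eqn{n_2} are the numbers of singleton and doubleton
#' taxa. The bias-corrected form is used so the estimator is defined when
#' no doubletons are observed.
#'
#' @inheritParams shannon
#' @return Estimated richness, at least `S_obs`.
#' @export
chao1 <- function(counts) {
  check_counts(counts)
  s_obs <- sum(counts > 0)
  n1 <- sum(counts == 1)
  n2 <- sum(counts == 2)
  s_obs + n1 * (n1 - 1) / (2 * (n2 + 1))
}

#' Good's coverage
#'
#' \eqn{C = 1 - n_1 / N}: the estimated fraction of the community
#' represented by the observed sample.
#'
#' @inheritParams shannon
#' @return Coverage in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  check_counts(counts)
  1 - sum(counts == 1) / sum(counts)
}

#' Alpha-diversity summary table
#'
#' Computes observed richness, Chao1, Good's coverage, Shannon and inverse
#' Simpson indices for every sample of a community table.
#'
#' @param x A [community_table()].
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(x) {
  m <- x$counts
  data.frame(
    sample_id = rownames(m),
    s_obs = apply(m, 1L, function(r) sum(r > 0)),
    chao1 = apply(m, 1L, chao1),
    goods_coverage = apply(m, 1L, goods_coverage),
    shannon = apply(m, 1L, shannon),
    inv_simpson = apply(m, 1L, inv_simpson),
    row.names = NULL
  )
}

#' Rarefaction curve for one sample
#'
#' Mean and SD of observed richness over repeated without-replacement
#' subsamples at each requested depth.
#'
#' @param counts Nonnegative integer vector of taxon counts.
#' @param depths Integer depths, each at most `sum(counts)`.
#' @param n_reps Number of subsampling replicates per depth.
#' @param seed Optional seed for reproducibility.
#' @return data.frame with columns `depth`, `mean_s_obs`, `sd_s_obs`.
#' @export
rarefaction_curve <- function(counts, depths, n_reps = 100L, seed = NULL) {
  check_counts(counts)
  n <- sum(counts)
  if (any(depths > n)) stop("depth exceeds library size", call. = FALSE)
  if (any(depths <= 0)) stop("depths must be positive", call. = FALSE)
  reads <- rep.int(seq_along(counts), counts)
  .with_seed(seed, {
    res <- lapply(depths, function(d) {
      rich <- replicate(n_reps, length(unique(sample(reads, d))))
      c(mean(rich), stats::sd(rich))
    })
    data.frame(depth = depths,
               mean_s_obs = vapply(res, `[`, 0, 1L),
               sd_s_obs = vapply(res, `[`, 0, 2L))
  })
}
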