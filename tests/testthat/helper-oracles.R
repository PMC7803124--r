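# Independent brute-force oracles, written deliberately differently from
# the package implementations, plus small fixture builders.

random_table <- function(n_samples, n_otus, seed, max_count = 50) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(n_samples * n_otus, lambda = runif(1, 2, 10)),
                n_samples, n_otus)
    m[sample(length(m), length(m) %/% 3)] <- 0
    if (all(rowSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      paste0("otu", seq_len(n_otus)))
  community_table(m)
}

bray_brute <- function(x, y) {
  a <- unname(x / sum(x))
  b <- unname(y / sum(y))
  num <- 0
  den <- 0
  for (k in seq_along(a)) {
    num <- num + abs(a[k] - b[k])
    den <- den + a[k] + b[k]
  }
  num / den
}

jaccard_brute <- function(x, y) {
  x <- unname(x); y <- unname(y)
  inter <- 0
  uni <- 0
  for (k in seq_along(x)) {
    if (x[k] > 0 && y[k] > 0) inter <- inter + 1
    if (x[k] > 0 || y[k] > 0) uni <- uni + 1
  }
  1 - inter / uni
}

theta_yc_brute <- function(x, y) {
  a <- unname(x / sum(x))
  b <- unname(y / sum(y))
  num <- 0
  dev <- 0
  for (k in seq_along(a)) {
    num <- num + a[k] * b[k]
    dev <- dev + (a[k] - b[k])^2
  }
  1 - num / (dev + num)
}

ols_brute <- function(t, y) {
  x <- cbind(1, t)
  beta <- solve(t(x) %*% x, t(x) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# AMOVA sums of squares / F statistic by explicit pair loops.
amova_brute <- function(d, labels) {
  n <- nrow(d)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + d[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (lev in unique(labels)) {
    idx <- which(labels == lev)
    acc <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + d[idx[a], idx[b]]^2
    ss_within <- ss_within + acc / length(idx)
  }
  k <- length(unique(labels))
  f <- ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
  list(ss_total = ss_total, ss_within = ss_within,
       ss_among = ss_total - ss_within, f = f)
}

homova_brute <- function(d, labels) {
  n <- nrow(d)
  levs <- unique(labels)
  s2 <- numeric(length(levs))
  for (li in seq_along(levs)) {
    idx <- which(labels == levs[li])
    acc <- 0
    for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
      acc <- acc + d[idx[a], idx[b]]^2
    s2[li] <- (acc / length(idx)) / (length(idx) - 1)
  }
  ngs <- as.vector(table(factor(labels, levels = levs)))
  k <- length(levs)
  pooled <- sum(s2 * (ngs - 1)) / (n - k)
  (n - k) * log(pooled) - sum((ngs - 1) * log(s2))
}

# Exact two-group permutation p-values by explicit enumeration of which
# samples carry the first label.
amova_p_brute <- function(d, labels) {
  lev <- unique(labels)
  stopifnot(length(lev) == 2)
  n1 <- sum(labels == lev[1])
  obs <- amova_brute(d, labels)$f
  sets <- combn(nrow(d), n1, simplify = FALSE)
  fs <- vapply(sets, function(s) {
    lab <- rep(lev[2], nrow(d))
    lab[s] <- lev[1]
    amova_brute(d, lab)$f
  }, 0)
  mean(fs >= obs - 1e-12)
}

homova_p_brute <- function(d, labels) {
  lev <- unique(labels)
  n1 <- sum(labels == lev[1])
  obs <- homova_brute(d, labels)
  sets <- combn(nrow(d), n1, simplify = FALSE)
  bs <- vapply(sets, function(s) {
    lab <- rep(lev[2], nrow(d))
    lab[s] <- lev[1]
    homova_brute(d, lab)
  }, 0)
  mean(bs >= obs - 1e-12)
}

# Procrustes error after optimal translation/rotation/reflection.
procrustes_error <- function(a, b) {
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  s <- svd(t(b) %*% a)
  rot <- s$u %*% t(s$v)
  sqrt(sum((b %*% rot - a)^2) / nrow(a))
}

# Euclidean distance matrix of a point cloud, with ids.
point_dist <- function(pts) {
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("p", seq_len(nrow(pts))),
                      paste0("p", seq_len(nrow(pts))))
  d
}
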