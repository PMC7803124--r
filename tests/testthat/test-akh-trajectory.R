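# Fixed small synthetic dataset reused across trajectory tests.
akh_fixture <- local({
  sim <- NULL
  function() {
    if (is.null(sim))
      sim <<- generate_communities(
        synthetic_config(depth = 400L, n_genera = 40L,
                         n_treatment_responders = 15L, seed = 77L))
    sim
  }
})

test_that("pair series enumerate the design combinatorics", {
  sim <- akh_fixture()
  tt <- build_pair_series(sim$table, sim$metadata, "bray_curtis",
                          tax = sim$taxonomy, rank = "genus",
                          pair_category = "treatment-treatment")
  expect_equal(nrow(tt), choose(3, 2) * 12)  # 36
  expect_true(all(tt$vessel_a != tt$vessel_b))

  tc <- build_pair_series(sim$table, sim$metadata, "bray_curtis",
                          tax = sim$taxonomy, rank = "genus",
                          pair_category = "treatment-control")
  expect_equal(nrow(tc), 3 * 3 * 12)

  wv <- build_pair_series(sim$table, sim$metadata, "bray_curtis",
                          tax = sim$taxonomy, rank = "genus",
                          pair_category = "within-vessel")
  expect_equal(nrow(wv), 6 * choose(12, 2))  # 66 points per vessel
  expect_true(all(wv$vessel_a == wv$vessel_b))
  expect_true(all(wv$time_h > 0))  # lags, distinct times only
})

test_that("replicate vessels give all-zero dissimilarity and null slopes", {
  # same counts in every vessel at a given time
  base <- matrix(rpois(12 * 10, 20) + 1L, 12, 10)
  counts <- base[rep(1:12, each = 6), ]
  times <- c(4, 12, 24, 28, 36, 48, 52, 60, 72, 76, 84, 96)
  vessels <- c("C1", "C2", "C3", "T1", "T2", "T3")
  md <- data.frame(
    sample_id = paste0(rep(vessels, 12), "_", rep(times, each = 6)),
    vessel = rep(vessels, 12),
    condition = rep(rep(c("control", "treatment"), each = 3), 12),
    day = rep(floor((times - 1e-9) / 24) + 1, each = 6),
    hours_post_feeding = rep(times - 24 * floor((times - 1e-9) / 24),
                             each = 6),
    time_h = rep(times, each = 6))
  dimnames(counts) <- list(md$sample_id, paste0("o", 1:10))
  tab <- community_table(counts)
  tt <- build_pair_series(tab, sample_metadata(md), "bray_curtis",
                          pair_category = "treatment-treatment")
  expect_true(all(tt$dissimilarity == 0))
  expect_equal(fit_slope(tt)$slope, 0)
  expect_equal(permutation_slope_test(tt, n_perm = 99, seed = 1), 1)
})

test_that("fit_slope matches exact lines and the normal equations", {
  t <- rep(c(0, 10, 20, 30), 2)
  s <- data.frame(time_h = t, dissimilarity = 0.001 * t + 0.2,
                  pair_id = rep(c("a", "b"), each = 4))
  f <- fit_slope(s)
  expect_equal(f$slope, 0.001, tolerance = 1e-12)
  expect_equal(f$intercept, 0.2, tolerance = 1e-12)

  s$dissimilarity <- 0.4
  expect_equal(fit_slope(s)$slope, 0)

  set.seed(3)
  s$dissimilarity <- runif(8)
  oracle <- ols_brute(s$time_h, s$dissimilarity)
  f2 <- fit_slope(s)
  expect_equal(f2$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(f2$intercept, unname(oracle["intercept"]),
               tolerance = 1e-12)

  expect_error(fit_slope(s[1:2, ]), "at least 3")
  s$time_h <- 5
  expect_error(fit_slope(s), "all times equal")
})

test_that("a deterministic trend attains the minimum permutation p", {
  t <- rep(c(4, 12, 24, 36, 48, 60, 72, 96), 3)
  s <- data.frame(time_h = t, dissimilarity = t / 100,
                  pair_id = rep(c("a", "b", "c"), each = 8))
  expect_equal(permutation_slope_test(s, n_perm = 999, seed = 5), 1e-3)
})

test_that("Monte-Carlo slope p approaches the exhaustive enumeration", {
  set.seed(11)
  s <- data.frame(time_h = rep(c(1, 2, 3), 2),
                  dissimilarity = c(0.1, 0.5, 0.4, 0.2, 0.3, 0.6),
                  pair_id = rep(c("a", "b"), each = 3))
  # enumerate all 36 within-pair time permutations
  perms <- expand.grid(a = 1:6, b = 1:6)
  all_perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                      c(3, 1, 2), c(3, 2, 1))
  obs <- abs(ols_brute(s$time_h, s$dissimilarity)["slope"])
  slopes <- apply(perms, 1, function(pr) {
    tp <- c(s$time_h[1:3][all_perms3[pr[1], ]],
            s$time_h[4:6][all_perms3[pr[2], ]])
    ols_brute(tp, s$dissimilarity)["slope"]
  })
  p_exact <- mean(abs(slopes) >= obs - 1e-15)
  p_mc <- permutation_slope_test(s, n_perm = 4000, seed = 13)
  expect_lt(abs(p_mc - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-3)
})

test_that("permutation and bootstrap are invariant to row order", {
  sim <- akh_fixture()
  tt <- build_pair_series(sim$table, sim$metadata, "bray_curtis",
                          tax = sim$taxonomy, rank = "genus",
                          pair_category = "treatment-treatment")
  shuf <- tt[sample(nrow(tt)), ]
  expect_identical(permutation_slope_test(tt, n_perm = 99, seed = 4),
                   permutation_slope_test(shuf, n_perm = 99, seed = 4))
  expect_identical(bootstrap_slope_ci(tt, n_boot = 99, seed = 4),
                   bootstrap_slope_ci(shuf, n_boot = 99, seed = 4))
})

test_that("bootstrap CI collapses on noiseless series and honours the point estimate", {
  t <- rep(c(0, 10, 20, 30), 3)
  s <- data.frame(time_h = t, dissimilarity = 0.002 * t + 0.1,
                  pair_id = rep(c("a", "b", "c"), each = 4))
  ci <- bootstrap_slope_ci(s, n_boot = 200, seed = 6)
  expect_equal(ci[["lo"]], 0.002, tolerance = 1e-12)
  expect_equal(ci[["hi"]], 0.002, tolerance = 1e-12)
  expect_error(bootstrap_slope_ci(s[s$pair_id == "a", ]),
               "at least 2 distinct")
})

test_that("bootstrap CI covers a known slope and widens with noise", {
  # moderate cluster count: percentile cluster bootstraps undercover
  # with very few clusters, so coverage is asserted against a floor
  times <- c(4, 12, 24, 28, 36, 48, 52, 60, 72, 76, 84, 96)
  cover <- 0
  widths <- matrix(0, 60, 2)
  for (r in 1:150) {
    set.seed(r)
    n_pairs <- 30
    t <- rep(times, n_pairs)
    pid <- rep(paste0("p", seq_len(n_pairs)), each = length(times))
    y <- 0.001 * t + rep(rnorm(n_pairs, 0, 0.05), each = length(times)) +
      rnorm(length(t), 0, 0.03)
    ci <- bootstrap_slope_ci(data.frame(time_h = t, dissimilarity = y,
                                        pair_id = pid),
                             n_boot = 200, seed = r)
    if (ci[["lo"]] <= 0.001 && 0.001 <= ci[["hi"]]) cover <- cover + 1
    if (r <= 60) {
      y2 <- 0.001 * t + rep(rnorm(n_pairs, 0, 0.05),
                            each = length(times)) +
        rnorm(length(t), 0, 0.12)
      ci2 <- bootstrap_slope_ci(data.frame(time_h = t,
                                           dissimilarity = y2,
                                           pair_id = pid),
                                n_boot = 200, seed = r + 1000)
      widths[r, ] <- c(ci[["hi"]] - ci[["lo"]],
                       ci2[["hi"]] - ci2[["lo"]])
    }
  }
  expect_gte(cover / 150, 0.90)
  expect_gt(mean(widths[, 2]), mean(widths[, 1]))
})

test_that("multi_rank_akh fills the full grid deterministically", {
  sim <- akh_fixture()
  grid <- multi_rank_akh(sim$table, sim$taxonomy, sim$metadata,
                         metric = "bray_curtis",
                         ranks = c("genus", "phylum"),
                         n_perm = 49L, n_boot = 49L, seed = 101L)
  expect_equal(nrow(grid), 2 * 4)
  expect_setequal(unique(grid$rank), c("genus", "phylum"))
  expect_true(all(grid$ci_lo <= grid$slope & grid$slope <= grid$ci_hi))
  expect_true(all(grid$p_value >= 1 / 50))
  grid2 <- multi_rank_akh(sim$table, sim$taxonomy, sim$metadata,
                          metric = "bray_curtis",
                          ranks = c("genus", "phylum"),
                          n_perm = 49L, n_boot = 49L, seed = 101L)
  expect_identical(grid, grid2)
  expect_error(multi_rank_akh(sim$table, sim$taxonomy, sim$metadata,
                              ranks = "kingdom"), "unsupported ranks")
})

test_that("dispersion peak estimation follows its tie and edge rules", {
  mk <- function(y_by_time) {
    times <- as.numeric(names(y_by_time))
    data.frame(time_h = rep(times, each = 3),
               dissimilarity = rep(y_by_time, each = 3) +
                 rep(c(-0.001, 0, 0.001), length(times)),
               pair_id = rep(c("a", "b", "c"), length(times)))
  }
  # monotone series: estimate is the last timepoint
  mono <- mk(stats::setNames(seq(0.2, 0.9, length.out = 8),
                             c(4, 12, 24, 36, 48, 60, 72, 96)))
  expect_equal(dispersion_peak_estimate(mono), 96)
  # constant series: ties broken to the earliest time
  const <- mk(stats::setNames(rep(0.5, 8),
                              c(4, 12, 24, 36, 48, 60, 72, 96)))
  expect_equal(dispersion_peak_estimate(const), 4)
  expect_error(dispersion_peak_estimate(mono[mono$time_h < 25, ]),
               "at least 4 distinct")
})

test_that("treatment vessels show the stronger time-lag trend", {
  stats <- akp_recovery_stats(100L)
  expect_gte(mean(stats$lag_slope_trt > stats$lag_slope_ctrl), 0.8)
})
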