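# Shared, memoized parameter-recovery sweep over seeds of the default
# synthetic configuration. Several test files assert different properties
# of the same sweep, so it is computed once per session.

.recovery_cache <- new.env(parent = emptyenv())

akp_recovery_stats <- function(n_seeds = 100L) {
  key <- paste0("seeds", n_seeds)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  res <- lapply(seq_len(n_seeds), function(s) {
    sim <- generate_communities(synthetic_config(seed = s))
    d <- pairwise_distances(sim$table, "bray_curtis", tax = sim$taxonomy,
                            rank = "genus")
    tt <- rumenAKP:::series_from_dist(d, sim$metadata,
                                      "treatment-treatment")
    wv <- rumenAKP:::series_from_dist(d, sim$metadata, "within-vessel")
    ctrl <- wv[grepl("^C", wv$pair_id), ]
    trt <- wv[grepl("^T", wv$pair_id), ]
    agg <- aggregate_to_rank(sim$table, sim$taxonomy, "phylum")
    rel <- 100 * agg$counts[, "Euryarchaeota"] / rowSums(agg$counts)
    cond <- sim$metadata$condition
    data.frame(
      tt_slope = fit_slope(tt)$slope,
      tt_p = permutation_slope_test(tt, n_perm = 199L, seed = s),
      peak_h = dispersion_peak_estimate(tt),
      tt72 = mean(tt$dissimilarity[tt$time_h == 72]),
      tt4 = mean(tt$dissimilarity[tt$time_h == 4]),
      lag_slope_ctrl = fit_slope(ctrl)$slope,
      lag_slope_trt = fit_slope(trt)$slope,
      eury_ctrl = mean(rel[cond == "control"]),
      eury_trt = mean(rel[cond == "treatment"]))
  })
  out <- do.call(rbind, res)
  .recovery_cache[[key]] <- out
  out
}
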