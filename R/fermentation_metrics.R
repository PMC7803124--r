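# Gas and VFA summaries: normalization, percent reduction, ratios,
# relative-abundance summaries and vessel-level permutation contrasts.

VFA_ACIDS <- c("acetate", "propionate", "butyrate", "isobutyrate",
               "valerate", "isovalerate")
GAS_RESPONSES <- c("ch4", "co2", "total_gas")

#' Construct a fermentation series
#'
#' Per-vessel time series of gas production (ml per g organic matter fed)
#' and VFA concentrations (ppm). Validates nonnegativity and the
#' component constraint `total_gas >= ch4`.
#'
#' @param df data.frame with columns `vessel`, `condition`, `day`,
#'   `hours_post_feeding`, `time_h`, `ch4`, `co2`, `total_gas` and the
#'   six VFA columns (acetate, propionate, butyrate, isobutyrate,
#'   valerate, isovalerate).
#' @return Object of class `fermentation_series` (a data.frame).
#' @export
fermentation_series <- function(df) {
  need <- c("vessel", "condition", "day", "hours_post_feeding", "time_h",
            GAS_RESPONSES, VFA_ACIDS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fermentation series missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[, need]
  if (!all(df$condition %in% c("control", "treatment")))
    stop("condition must be 'control' or 'treatment'", call. = FALSE)
  vals <- as.matrix(df[, c(GAS_RESPONSES, VFA_ACIDS)])
  if (anyNA(vals) || any(vals < 0))
    stop("gas and VFA values must be nonnegative", call. = FALSE)
  if (any(df$total_gas < df$ch4 - 1e-9))
    stop("total_gas must be at least ch4", call. = FALSE)
  structure(df, class = c("fermentation_series", "data.frame"))
}

#' Read / write a fermentation TSV
#' @param path File path.
#' @return A [fermentation_series()] for `read_fermentation`.
#' @export
read_fermentation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"time_h" %in% names(df))
    df$time_h <- 24 * (df$day - 1) + df$hours_post_feeding
  fermentation_series(df)
}

#' @rdname read_fermentation
#' @param series A `fermentation_series`.
#' @export
write_fermentation <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Normalise a gas volume per gram of organic matter fed
#'
#' @param volume_ml Measured volume in ml.
#' @param grams_om_fed Organic matter fed, in grams (> 0).
#' @return Volume in ml/(g OM).
#' @export
normalize_per_g_om <- function(volume_ml, grams_om_fed) {
  if (any(grams_om_fed <= 0))
    stop("grams_om_fed must be positive", call. = FALSE)
  volume_ml / grams_om_fed
}

#' Percent reduction of a response under treatment
#'
#' `100 * (control_mean - treatment_mean) / control_mean`. Negative
#' values indicate an increase under treatment.
#'
#' @param control_mean Control group mean (> 0).
#' @param treatment_mean Treatment group mean.
#' @return Percent reduction.
#' @examples
#' percent_reduction(12.08, 0.59)  # ~95.1
#' @export
percent_reduction <- function(control_mean, treatment_mean) {
  if (any(control_mean <= 0))
    stop("control_mean must be positive", call. = FALSE)
  100 * (control_mean - treatment_mean) / control_mean
}

#' Propionate:acetate ratio per record and by condition
#'
#' The ratio is computed per record and then averaged within condition
#' (mean of ratios). This is deliberately not the ratio of group means:
#' with correlated within-sample variation the two differ, and the
#' per-record form is the one a per-sample assay reports.
#'
#' @param series A [fermentation_series()] with positive acetate in every
#'   record.
#' @return List with `per_record` (data.frame vessel, condition, time_h,
#'   ratio) and `group_means` (named numeric, one per condition).
#' @export
propionate_acetate_ratio <- function(series) {
  if (any(series$acetate <= 0))
    stop("acetate must be positive in every record", call. = FALSE)
  ratio <- series$propionate / series$acetate
  per_record <- data.frame(vessel = series$vessel,
                           condition = series$condition,
                           time_h = series$time_h, ratio = ratio)
  list(per_record = per_record,
       group_means = tapply(ratio, series$condition, mean))
}

#' Vessel-level permutation contrast of a fermentation response
#'
#' The effect is the difference of condition means of per-vessel average
#' responses (treatment minus control). The p-value permutes condition
#' labels across vessels -- the vessel is the exchangeable unit -- either
#' exhaustively (all `choose(n, n_trt)` relabellings, exact p, observed
#' labelling included) when that count is within `n_perm` or
#' `exhaustive = TRUE`, or by Monte-Carlo sampling with the add-one
#' convention otherwise. Two-sided by `|effect|`.
#'
#' @param series A [fermentation_series()].
#' @param response Column name, e.g. `"ch4"` or `"acetate"`.
#' @param n_perm Permutation budget (default 1000).
#' @param seed Optional seed (Monte-Carlo mode only).
#' @param exhaustive Force or forbid enumeration; `NULL` (default)
#'   enumerates when feasible within `n_perm`.
#' @return List with `effect`, `p_value`, `method`, `n_permutations`,
#'   `vessel_means`.
#' @export
treatment_contrast <- function(series, response, n_perm = 1000L,
                               seed = NULL, exhaustive = NULL) {
  if (!response %in% names(series))
    stop("unknown response '", response, "'", call. = FALSE)
  vm <- tapply(series[[response]], series$vessel, mean)
  vc <- tapply(series$condition, series$vessel, function(x) x[1])
  if (length(unique(vc)) < 2L)
    stop("both conditions must be present", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  n <- length(vm)
  trt <- which(vc == "treatment")
  obs <- mean(vm[trt]) - mean(vm[-trt])
  n_exh <- choose(n, length(trt))
  use_exh <- if (is.null(exhaustive)) n_exh <= n_perm else exhaustive
  if (use_exh) {
    sets <- utils::combn(n, length(trt), simplify = FALSE)
    effs <- vapply(sets, function(s) mean(vm[s]) - mean(vm[-s]), 0)
    p <- mean(abs(effs) >= abs(obs) - 1e-12)
    method <- "exhaustive"
    n_used <- length(sets)
  } else {
    exceed <- .with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(b) {
        s <- sample.int(n, length(trt))
        abs(mean(vm[s]) - mean(vm[-s])) >= abs(obs) - 1e-12
      }, NA))
    })
    p <- (exceed + 1) / (n_perm + 1)
    method <- "sampled"
    n_used <- as.integer(n_perm)
  }
  list(effect = unname(obs), p_value = p, method = method,
       n_permutations = n_used, vessel_means = vm)
}

#' Mean relative abundance of a taxon by condition
#'
#' Aggregates the community table to `rank`, computes the taxon's
#' per-sample relative abundance (taxon count / library size, in
#' percent), and averages within condition. A taxon present in the
#' taxonomy but recruiting no reads reports 0%.
#'
#' @param x A [community_table()].
#' @param tax A [taxonomy_map()].
#' @param metadata A [sample_metadata()] covering all samples.
#' @param taxon Taxon name at `rank` (e.g. `"Euryarchaeota"`).
#' @param rank Taxonomic rank of `taxon`.
#' @return data.frame with one row per condition: `condition`,
#'   `mean_pct`, `se_pct`, `n_samples`.
#' @export
relative_abundance_summary <- function(x, tax, metadata, taxon, rank) {
  if (!taxon %in% tax[[rank]])
    stop("taxon '", taxon, "' not found at rank '", rank, "'",
         call. = FALSE)
  agg <- aggregate_to_rank(x, tax, rank)
  rel <- if (taxon %in% otu_ids(agg)) {
    100 * agg$counts[, taxon] / rowSums(agg$counts)
  } else {
    stats::setNames(rep(0, nrow(agg$counts)), sample_ids(agg))
  }
  md <- align_metadata(metadata, sample_ids(agg))
  out <- do.call(rbind, lapply(split(rel, md$condition), function(v) {
    data.frame(mean_pct = mean(v),
               se_pct = stats::sd(v) / sqrt(length(v)),
               n_samples = length(v))
  }))
  data.frame(condition = rownames(out), out, row.names = NULL)
}

#' Fermentation summary table with permutation contrasts
#'
#' Group means, per-group and pooled standard errors (of the vessel-level
#' means), and a vessel-level permutation p-value for every gas and VFA
#' response, plus the propionate:acetate mean-of-ratios row.
#'
#' @param series A [fermentation_series()].
#' @param n_perm Permutation budget per response.
#' @param seed Optional base seed.
#' @return data.frame with one row per response.
#' @export
fermentation_summary <- function(series, n_perm = 1000L, seed = NULL) {
  responses <- c(GAS_RESPONSES, VFA_ACIDS)
  rows <- lapply(seq_along(responses), function(i) {
    r <- responses[i]
    ct <- treatment_contrast(series, r, n_perm = n_perm,
                             seed = if (is.null(seed)) NULL
                                    else derive_seed(seed, i))
    vm <- ct$vessel_means
    vc <- tapply(series$condition, series$vessel, function(x) x[1])
    mc <- vm[vc == "control"]
    mt <- vm[vc == "treatment"]
    pooled_var <- (sum((mc - mean(mc))^2) + sum((mt - mean(mt))^2)) /
      (length(vm) - 2)
    data.frame(response = r,
               control_mean = mean(mc), treatment_mean = mean(mt),
               se_control = stats::sd(mc) / sqrt(length(mc)),
               se_treatment = stats::sd(mt) / sqrt(length(mt)),
               # pooled SD over the average group size: one SE per response
               se_pooled = sqrt(pooled_var / ((length(mc) + length(mt)) / 2)),
               pct_reduction = percent_reduction(mean(mc), mean(mt)),
               p_value = ct$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pa <- propionate_acetate_ratio(series)$group_means
  rbind(out, data.frame(response = "propionate_acetate",
                        control_mean = unname(pa["control"]),
                        treatment_mean = unname(pa["treatment"]),
                        se_control = NA, se_treatment = NA, se_pooled = NA,
                        pct_reduction = percent_reduction(
                          pa[["control"]], pa[["treatment"]]),
                        p_value = NA, stringsAsFactors = FALSE))
}
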