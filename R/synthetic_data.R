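# Dirichlet-multinomial synthetic communities and fermentation series
# emulating a 6-vessel, 2-condition, 12-timepoint in-vitro rumen design.

METHANOGEN_GENERA <- c("Methanobrevibacter", "Methanosphaera", "vadinCA11",
                       "Methanoplanus", "Methanimicrococcus")

default_gas_params <- function() {
  # means ml/(g OM); per-record SD = sqrt(3) x the pooled SE of a
  # 3-vessel group mean, read as the between-vessel spread
  list(ch4 = c(control = 12.08, treatment = 0.59, sd = 0.59 * sqrt(3)),
       co2 = c(control = 15.67, treatment = 14.24, sd = 3.82 * sqrt(3)),
       total_gas = c(control = 28.54, treatment = 14.81,
                     sd = 3.85 * sqrt(3)))
}

default_vfa_params <- function() {
  # means ppm; SDs as above
  list(acetate = c(control = 1056.99, treatment = 856.77,
                   sd = 135.08 * sqrt(3)),
       propionate = c(control = 481.12, treatment = 490.54,
                      sd = 58.36 * sqrt(3)),
       butyrate = c(control = 394.35, treatment = 423.01,
                    sd = 53.55 * sqrt(3)),
       isobutyrate = c(control = 84.81, treatment = 79.83,
                       sd = 4.32 * sqrt(3)),
       valerate = c(control = 212.79, treatment = 168.72,
                    sd = 16.99 * sqrt(3)),
       isovalerate = c(control = 102.44, treatment = 86.21,
                       sd = 14.49 * sqrt(3)))
}

#' Configuration for the synthetic-data generator
#'
#' Encodes the study design the generator emulates: 3 vessels per
#' condition sampled at 4, 12 and 24 h post feeding over 4 days (12 time
#' points), rarefied depth 6467 reads per sample, ~120 genera spanning
#' the dominant rumen phyla plus five methanogen genera under
#' Euryarchaeota. Treatment effects: a tent-shaped dispersion increase
#' peaking at `akp_peak_h` (Anna-Karenina effect, implemented by dividing
#' the Dirichlet concentration), a log2 depletion of methanogen mean
#' abundance, and a slow treatment-specific compositional drift; both
#' conditions share a Bacteroidetes:Firmicutes drift.
#'
#' @param n_vessels_per_condition Vessels per condition (default 3).
#' @param timepoints_h Sampling times, hours since start.
#' @param depth Reads per sample (default 6467).
#' @param n_genera Total number of genera including the 5 methanogens.
#' @param base_concentration Dirichlet concentration scale (default 50);
#'   smaller means more between-vessel dispersion.
#' @param akp_peak_h Time of peak treatment dispersion (default 72).
#' @param akp_strength Dispersion multiplier at the peak (>= 1, default
#'   4); 1 disables the effect.
#' @param methanogen_log2_depletion Log2 reduction of treatment
#'   methanogen share (default 0.4); 0 disables.
#' @param methanogen_baseline Control-arm total methanogen relative
#'   abundance (default 0.0179).
#' @param bf_drift_rate Shared per-day log-scale shrinkage of
#'   Bacteroidetes genera (default 0.20), driving the declining
#'   Bacteroidetes:Firmicutes ratio.
#' @param treatment_drift_rate Per-day log-scale growth rate of the
#'   responder genera in treatment vessels only (default 0.80); 0
#'   disables. Responders are the rarest bulk genera, so the treatment
#'   community slowly gains blooming opportunists.
#' @param n_treatment_responders Number of responder genera (default 50).
#' @param phylum_weights Named weights for assigning bulk genera to
#'   phyla.
#' @param methanogen_split Within-methanogen composition; defaults put
#'   >99% of methanogen reads in Methanobrevibacter + Methanosphaera.
#' @param gas_params,vfa_params Per-response control/treatment means and
#'   per-record SDs (gas in ml/(g OM), VFA in ppm); defaults are the
#'   observed group means of the emulated experiment.
#' @param seed Integer seed; all outputs are bit-reproducible given it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_vessels_per_condition = 3L,
                             timepoints_h = c(4, 12, 24, 28, 36, 48, 52,
                                              60, 72, 76, 84, 96),
                             depth = 6467L,
                             n_genera = 120L,
                             base_concentration = 50,
                             akp_peak_h = 72,
                             akp_strength = 4,
                             methanogen_log2_depletion = 0.4,
                             methanogen_baseline = 0.0179,
                             bf_drift_rate = 0.20,
                             treatment_drift_rate = 0.80,
                             n_treatment_responders = 50L,
                             phylum_weights = c(Bacteroidetes = 0.50,
                                                Firmicutes = 0.35,
                                                Proteobacteria = 0.10,
                                                Spirochaetes = 0.03,
                                                Actinobacteria = 0.02),
                             methanogen_split = c(
                               Methanobrevibacter = 0.800,
                               Methanosphaera = 0.195,
                               vadinCA11 = 0.003,
                               Methanoplanus = 0.001,
                               Methanimicrococcus = 0.001),
                             gas_params = default_gas_params(),
                             vfa_params = default_vfa_params(),
                             seed = 1L) {
  cfg <- list(n_vessels_per_condition = as.integer(n_vessels_per_condition),
              timepoints_h = as.numeric(timepoints_h),
              depth = as.integer(depth), n_genera = as.integer(n_genera),
              base_concentration = base_concentration,
              akp_peak_h = akp_peak_h, akp_strength = akp_strength,
              methanogen_log2_depletion = methanogen_log2_depletion,
              methanogen_baseline = methanogen_baseline,
              bf_drift_rate = bf_drift_rate,
              treatment_drift_rate = treatment_drift_rate,
              n_treatment_responders = as.integer(n_treatment_responders),
              phylum_weights = phylum_weights,
              methanogen_split = methanogen_split,
              gas_params = gas_params, vfa_params = vfa_params,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$depth <= 0) stop("depth must be positive", call. = FALSE)
  if (cfg$akp_strength < 1) stop("akp_strength must be >= 1", call. = FALSE)
  if (cfg$n_vessels_per_condition < 1)
    stop("need at least one vessel per condition", call. = FALSE)
  if (cfg$n_genera < length(METHANOGEN_GENERA) + 2L)
    stop("n_genera too small for the taxonomy seedlist", call. = FALSE)
  if (!setequal(names(cfg$methanogen_split), METHANOGEN_GENERA))
    stop("methanogen_split must name exactly the five methanogen genera",
         call. = FALSE)
  if (abs(sum(cfg$methanogen_split) - 1) > 1e-9)
    stop("methanogen_split must sum to 1", call. = FALSE)
  if (cfg$methanogen_baseline <= 0 || cfg$methanogen_baseline >= 1)
    stop("methanogen_baseline must lie in (0, 1)", call. = FALSE)
  if (is.null(names(cfg$phylum_weights)) || any(cfg$phylum_weights <= 0))
    stop("phylum_weights must be named and positive", call. = FALSE)
  if (cfg$n_treatment_responders >
      cfg$n_genera - length(METHANOGEN_GENERA))
    stop("more responders than bulk genera", call. = FALSE)
  sds <- c(vapply(cfg$gas_params, `[`, 0, "sd"),
           vapply(cfg$vfa_params, `[`, 0, "sd"))
  if (any(sds < 0)) stop("SDs must be nonnegative", call. = FALSE)
  invisible(cfg)
}

#' Null configuration: treatment and control exchangeable
#'
#' Disables every treatment effect (dispersion tent, methanogen
#' depletion, treatment drift) so that downstream tests see exchangeable
#' conditions; used for type-I-error calibration.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_null_config <- function(...) {
  synthetic_config(akp_strength = 1, methanogen_log2_depletion = 0,
                   treatment_drift_rate = 0, ...)
}

# Tent function: 1 at the peak, falling linearly with slope 1/width on
# both sides, floored at 0.
tent <- function(t, peak, width) pmax(0, 1 - abs(t - peak) / width)

# Deterministic synthetic lineage for a genus: mid-ranks group genera
# within a phylum in threes (family) and nines (order), one class per
# phylum.
synth_lineage <- function(genus, phylum, idx, kingdom) {
  fam <- paste0(phylum, "_fam", (idx - 1L) %/% 3L + 1L)
  ord <- paste0(phylum, "_ord", (idx - 1L) %/% 9L + 1L)
  cls <- paste0(phylum, "_cls1")
  paste(kingdom, phylum, cls, ord, fam, genus, sep = ";")
}

#' Generate synthetic community data
#'
#' Draws one sample per (vessel, time point). The mean composition per
#' condition and time is built from a fixed log-normal rank-abundance
#' profile with: the methanogen block pinned to an exact share
#' (`methanogen_baseline`, times `2^-methanogen_log2_depletion` in
#' treatment), a shared log-linear Bacteroidetes shrinkage, and a
#' treatment-only responder drift. Vessel compositions are Dirichlet
#' draws around that mean with concentration `base_concentration`,
#' divided in treatment by `1 + (akp_strength - 1) * tent(t)` so
#' between-vessel dispersion peaks at `akp_peak_h`; counts are
#' multinomial at `depth` reads.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `table` ([community_table()]), `taxonomy`
#'   ([taxonomy_map()]) and `metadata` ([sample_metadata()]).
#' @export
generate_communities <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  n_meth <- length(METHANOGEN_GENERA)
  n_bulk <- cfg$n_genera - n_meth
  withr::with_seed(cfg$seed, {
    # fixed taxonomy and base abundances
    pw <- cfg$phylum_weights / sum(cfg$phylum_weights)
    phyla <- sample(names(pw), n_bulk, replace = TRUE, prob = pw)
    bulk_names <- paste0(tolower(substr(phyla, 1, 4)), "_genus",
                         sprintf("%03d", seq_len(n_bulk)))
    base_ab <- exp(stats::rnorm(n_bulk, 0, 1.5))
    bulk_p <- base_ab / sum(base_ab)
    # opportunist responders: the rarest bulk genera bloom under the
    # stressor, so the treatment mean composition drifts away from both
    # its own start and the control trajectory
    responders <- order(bulk_p)[seq_len(cfg$n_treatment_responders)]
    resp_sign <- rep(1, cfg$n_treatment_responders)
    is_bact <- phyla == "Bacteroidetes"

    vessels <- c(paste0("C", seq_len(cfg$n_vessels_per_condition)),
                 paste0("T", seq_len(cfg$n_vessels_per_condition)))
    conditions <- rep(c("control", "treatment"),
                      each = cfg$n_vessels_per_condition)
    width <- cfg$akp_peak_h - min(cfg$timepoints_h)
    if (width <= 0) width <- 1

    counts <- NULL
    meta <- NULL
    for (ti in seq_along(cfg$timepoints_h)) {
      t <- cfg$timepoints_h[ti]
      day_frac <- t / 24
      for (vi in seq_along(vessels)) {
        cond <- conditions[vi]
        bulk_t <- bulk_p
        bulk_t[is_bact] <- bulk_t[is_bact] *
          exp(-cfg$bf_drift_rate * day_frac)
        if (cond == "treatment" && cfg$treatment_drift_rate > 0)
          bulk_t[responders] <- bulk_t[responders] *
            exp(resp_sign * cfg$treatment_drift_rate * day_frac)
        meth_share <- cfg$methanogen_baseline *
          if (cond == "treatment") 2^(-cfg$methanogen_log2_depletion) else 1
        mean_comp <- c(cfg$methanogen_split * meth_share,
                       bulk_t / sum(bulk_t) * (1 - meth_share))
        conc <- cfg$base_concentration
        if (cond == "treatment" && cfg$akp_strength > 1)
          conc <- conc / (1 + (cfg$akp_strength - 1) *
                            tent(t, cfg$akp_peak_h, width))
        gam <- stats::rgamma(length(mean_comp), shape = conc * mean_comp)
        p <- gam / sum(gam)
        counts <- rbind(counts, as.integer(stats::rmultinom(1L, cfg$depth,
                                                            p)))
        meta <- rbind(meta, data.frame(
          sample_id = sprintf("%s_%03.0fh", vessels[vi], t),
          vessel = vessels[vi], condition = cond,
          day = floor((t - 1e-9) / 24) + 1,
          hours_post_feeding = t - 24 * floor((t - 1e-9) / 24),
          time_h = t, stringsAsFactors = FALSE))
      }
    }
    genus_names <- c(METHANOGEN_GENERA, bulk_names)
    dimnames(counts) <- list(meta$sample_id, genus_names)
    meth_idx <- seq_len(n_meth)
    lineages <- c(
      vapply(meth_idx, function(i) synth_lineage(
        METHANOGEN_GENERA[i], "Euryarchaeota", i, "Archaea"), ""),
      vapply(seq_len(n_bulk), function(i) synth_lineage(
        bulk_names[i], phyla[i], i, "Bacteria"), ""))
    list(table = community_table(counts),
         taxonomy = taxonomy_map(genus_names, lineages),
         metadata = sample_metadata(meta))
  })
}

# One truncated-at-zero normal draw per element (inverse-CDF method); an
# SD of zero returns the mean exactly.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Generate a synthetic fermentation series
#'
#' Per vessel and time point, draws CH4, CO2 and each VFA from normal
#' distributions truncated at zero around the configured condition means;
#' total gas is the sum of the CH4 and CO2 draws, so the component
#' constraint holds by construction. Truncation shifts realised means
#' above the configured mean only when mean/SD is small (the treatment
#' CH4 arm); all comparisons in this package are permutation-based and
#' unaffected.
#'
#' @param config A [synthetic_config()].
#' @return A [fermentation_series()] data.frame.
#' @export
generate_fermentation <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  vessels <- c(paste0("C", seq_len(cfg$n_vessels_per_condition)),
               paste0("T", seq_len(cfg$n_vessels_per_condition)))
  conditions <- rep(c("control", "treatment"),
                    each = cfg$n_vessels_per_condition)
  grid <- expand.grid(vi = seq_along(vessels),
                      t = cfg$timepoints_h, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  cond <- conditions[grid$vi]
  draw <- function(par) {
    out <- numeric(n)
    for (cc in c("control", "treatment")) {
      idx <- cond == cc
      out[idx] <- rtruncnorm0(sum(idx), par[[cc]], par[["sd"]])
    }
    out
  }
  withr::with_seed(derive_seed(cfg$seed, 104729L), {
    ch4 <- draw(cfg$gas_params$ch4)
    co2 <- draw(cfg$gas_params$co2)
    vfa <- lapply(cfg$vfa_params, draw)
    df <- data.frame(
      vessel = vessels[grid$vi], condition = cond,
      day = floor((grid$t - 1e-9) / 24) + 1,
      hours_post_feeding = grid$t - 24 * floor((grid$t - 1e-9) / 24),
      time_h = grid$t,
      ch4 = ch4, co2 = co2, total_gas = ch4 + co2,
      stringsAsFactors = FALSE)
    for (acid in names(vfa)) df[[acid]] <- vfa[[acid]]
    fermentation_series(df)
  })
}

#' Write a full synthetic dataset to disk
#'
#' Emits the shared table, taxonomy TSV, metadata TSV and fermentation
#' TSV for a configuration, the file set the pipeline consumes.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the four paths.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_communities(config)
  ferm <- generate_fermentation(config)
  paths <- c(shared = file.path(dir, "community.shared"),
             taxonomy = file.path(dir, "community.taxonomy.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             fermentation = file.path(dir, "fermentation.tsv"))
  write_shared(sim$table, paths["shared"])
  write_taxonomy(sim$taxonomy, paths["taxonomy"])
  write_metadata(sim$metadata, paths["metadata"])
  write_fermentation(ferm, paths["fermentation"])
  invisible(paths)
}
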