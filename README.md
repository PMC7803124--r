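# rumenAKP

Microbiome-dynamics and fermentation analysis for semi-continuous
in-vitro rumen (RUSITEC) experiments that compare a treatment amendment
(e.g. a methane-suppressing seaweed) against control vessels. The
package targets the standard design of such studies — a few vessels per
arm, sampled at 4, 12 and 24 h after each daily feeding over four days —
and provides, for microbiologists and animal scientists running them:

- **alpha diversity**: observed richness, bias-corrected Chao1, Good's
  coverage, Shannon (natural log), inverse Simpson, rarefaction curves;
- **beta diversity**: Bray–Curtis, Jaccard and Yue–Clayton
  (1 − θ_YC) dissimilarities on rarefied relative abundances, at the OTU
  level or aggregated to genus…phylum;
- **distance-matrix inference**: AMOVA
  (F = [SS_among/(k−1)] / [SS_within/(N−k)] on squared pairwise
  distances, permutation null), HOMOVA (Bartlett-style B on within-group
  dispersions), and PCoA via Gower double-centering;
- **Anna-Karenina trajectory analysis**: β-diversity between vessel
  pairs over time and within vessels across time lags, with OLS slopes,
  within-pair permutation tests, cluster-bootstrap 95% CIs, and a
  smoothed estimator of the dispersion peak time;
- **fermentation summaries**: ml/(g OM) normalisation, percent
  reduction, per-record propionate:acetate ratios, vessel-level
  permutation contrasts (exact at 3v3);
- **a Dirichlet-multinomial synthetic-data generator** reproducing the
  design (6 vessels × 2 conditions × 12 time points, 6467 reads/sample,
  methanogen genera under Euryarchaeota, a tent-shaped treatment
  dispersion peak near 72 h, CH₄ strongly suppressed in treatment), so
  every stage is testable and its power measurable;
- **a one-command pipeline** (`run_pipeline()`, plus a thin CLI under
  `inst/cli/`) producing tables, distance files, test reports and
  figure-ready TSVs with a full reproducibility manifest.

File formats are the mothur-style exchange set: `.shared` OTU tables,
two-column taxonomy TSVs, PHYLIP square distance files, plain TSV
metadata and fermentation tables.

## Worked example

```r
library(rumenAKP)

cfg <- synthetic_config(seed = 42)       # the emulated study design
sim <- generate_communities(cfg)         # table + taxonomy + metadata
sim$table
#> community_table: 72 samples x 120 OTUs, total reads 465624

head(alpha_diversity(sim$table), 3)
#>   sample_id s_obs chao1 goods_coverage shannon inv_simpson
#> 1   C1_004h    61 70.33         0.9988   3.168       16.04
#> 2   C2_004h    60 75.00         0.9985   3.174       15.95
#> 3   C3_004h    64 71.50         0.9991   3.301       18.40

# Anna-Karenina trajectories at genus level
akh <- multi_rank_akh(sim$table, sim$taxonomy, sim$metadata,
                      ranks = "genus", n_perm = 999, n_boot = 999, seed = 1)
akh[, c("pair_category", "n_points", "slope", "ci_lo", "ci_hi", "p_value")]
#>         pair_category n_points     slope     ci_lo     ci_hi p_value
#> 1 treatment-treatment       36  0.002927  2.70e-03  0.003129   0.001
#> 2     control-control       36 -0.000597 -7.15e-04 -0.000496   0.040
#> 3   treatment-control      108  0.002979  2.73e-03  0.003264   0.001
#> 4       within-vessel      396  0.000356  2.67e-05  0.000686   0.039
```

Treatment-pair and treatment-vs-control dissimilarity rise strongly
(slopes ~0.003/h, p = 0.001, the add-one floor at 999 permutations)
while control pairs stay flat — the Anna-Karenina signature. The
dispersion peak lands on the configured 72 h:

```r
tt <- build_pair_series(sim$table, sim$metadata, "bray_curtis",
                        tax = sim$taxonomy, rank = "genus",
                        pair_category = "treatment-treatment")
dispersion_peak_estimate(tt)
#> [1] 72

relative_abundance_summary(sim$table, sim$taxonomy, sim$metadata,
                           "Euryarchaeota", "phylum")
#>   condition mean_pct se_pct n_samples
#> 1   control     2.19  0.415        36
#> 2 treatment     1.63  0.374        36

fs <- fermentation_summary(generate_fermentation(cfg), n_perm = 999, seed = 1)
fs[fs$response %in% c("ch4", "total_gas"),
   c("response", "control_mean", "treatment_mean", "pct_reduction", "p_value")]
#>    response control_mean treatment_mean pct_reduction p_value
#> 1       ch4      12.3521         1.3564         89.02     0.1
#> 3 total_gas      28.5900        16.8714         40.99     0.1

percent_reduction(12.08, 0.59)   # on reference group means
#> [1] 95.11589
```

The p of 0.1 on CH₄ is the exact two-sided floor of a 3-vs-3 vessel
permutation test (2 of the 20 relabellings reach |effect|); Euryarchaeota
mean abundance is depleted in treatment while methanogen depletion
(2^−0.4 ≈ 0.76×) is far milder than the ~90–95% CH₄ suppression — the
generator reproduces that deliberate decoupling.

Condition structure on a Yue–Clayton distance matrix:

```r
d <- pairwise_distances(sim$table, "theta_yc", tax = sim$taxonomy, rank = "genus")
amova(d, setNames(sim$metadata$condition, sim$metadata$sample_id),
      n_perm = 999, seed = 1)
#> AMOVA: SS_among 1.081 (df 1), SS_within 16.2 (df 70), F = 4.669, p = 0.001 (999 permutations)
pcoa(d)
#> PCoA: 72 samples, 44 positive axes; first 2 axes explain 21.4% of variance
```

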