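---
title: "Methods: microbiome dynamics and fermentation analysis for in-vitro rumen experiments"
author: "rumenAKP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiome dynamics and fermentation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenAKP)
```

## The analysis problem

Semi-continuous in-vitro rumen fermenters (RUSITEC) make it possible to
watch a rumen microbial community respond to a dietary intervention --
here, a methane-suppressing seaweed amendment -- under controlled
conditions: a handful of vessels per arm, sampled a few times per feeding
cycle over several days, with 16S rRNA OTU tables on the microbial side
and gas/volatile-fatty-acid (VFA) measurements on the chemical side.

`rumenAKP` packages the statistical core of such an analysis:

* within-sample (alpha) diversity: observed richness, bias-corrected
  Chao1, Good's coverage, Shannon (natural log), inverse Simpson;
* between-sample (beta) dissimilarity -- Bray-Curtis, Jaccard, and the
  Yue-Clayton measure used as a distance ($1-\theta_{YC}$) -- at the OTU
  level or aggregated to any taxonomic rank;
* inference on distance matrices: AMOVA, HOMOVA, and principal
  coordinate analysis;
* the *Anna-Karenina* trajectory analysis: dissimilarity between vessel
  pairs over time and within vessels across time lags, with permutation
  slope tests and cluster-bootstrap confidence intervals;
* fermentation summaries: per-g-organic-matter normalisation, percent
  reduction, propionate:acetate ratios, and vessel-level permutation
  contrasts;
* a Dirichlet-multinomial synthetic-data generator that emulates the
  6-vessel, 2-condition, 12-timepoint design, so every stage is testable
  and its power measurable without access to the original sequence
  deposit.

## Statistical models and procedures

### Dissimilarities

All abundance-based dissimilarities are computed on per-sample relative
abundances after rarefying to a common depth. Rationale: rarefying plus
proportions removes library-size artifacts, and the emulated pipeline
rarefies before community comparison. A raw-counts mode
(`proportions = FALSE`) exists for sensitivity checks only.

For relative abundances $a_i$, $b_i$:

* Bray-Curtis: $d = \sum_i |a_i - b_i| \, / \, \sum_i (a_i + b_i)$;
* Jaccard: $1 - |A \cap B| / |A \cup B|$ on presence sets (membership
  only);
* Yue-Clayton: $d = 1 - \sum a_i b_i / (\sum (a_i-b_i)^2 + \sum a_i
  b_i)$, reported as a distance (mothur convention).

### AMOVA and HOMOVA

AMOVA partitions squared pairwise distances: $SS_{total} =
\frac{1}{N}\sum_{i<j} d_{ij}^2$, $SS_{within} = \sum_g
\frac{1}{n_g}\sum_{i<j\in g} d_{ij}^2$, and
$F = \frac{SS_{among}/(k-1)}{SS_{within}/(N-k)}$, with significance from
random relabelling of group membership. HOMOVA compares within-group
dispersions $s^2_g = SSw_g/(n_g-1)$ through a Bartlett-style statistic
$B = (N-k)\ln s^2_p - \sum_g (n_g-1)\ln s^2_g$, again with a permutation
null.

Permutation p-values use the add-one convention
$p = (\#\{T^* \ge T\} + 1)/(n_{perm}+1)$, so $p$ is never zero and the
test is exact-level. When the number of distinct relabellings is small
(for example $\binom{6}{3} = 20$ at three vessels per arm) the
`exhaustive = TRUE` mode enumerates all of them and reports the exact
permutation p with the observed labelling included and no add-one term.

A point worth noting: when *all* pairwise distances are equal, the
distance-based $SS_{among}$ is a positive constant, not zero (equidistant
points are a regular simplex; any two group centroids differ). The
correct "no structure" diagnostic is that every relabelling yields the
identical $F$, so the permutation p is 1 -- which is what the test suite
asserts.

### Principal coordinates

Gower double-centering of $-\tfrac{1}{2}d_{ij}^2$ followed by
eigendecomposition. Axes are ordered by eigenvalue; negative eigenvalues
(Bray-Curtis and Yue-Clayton matrices are generally non-Euclidean) are
reported but excluded from the percent-variance denominators, and no
Lingoes/Cailliez correction is applied. Coordinates reproduce the input
distances exactly when the matrix is Euclidean-embeddable.

### Trajectory (Anna-Karenina) analysis

The Anna-Karenina principle predicts that a stressor increases
*between-replicate* variability rather than moving all communities the
same way. The analysis quantifies this with four point series:

* **between-vessel** series (treatment-treatment, control-control,
  treatment-control): one dissimilarity per vessel pair per shared
  nominal time point -- no interpolation across times;
* **within-vessel** series: one dissimilarity per sample pair of a
  vessel, indexed by the time lag $|t_a - t_b|$.

Each series gets an ordinary least-squares slope of dissimilarity on
time (or lag), a two-sided permutation test, and a 95% bootstrap CI:

* *Permutation unit*: time labels are shuffled **within each vessel
  pair's sub-series**. Points sharing a vessel pair are dependent;
  within-pair shuffling preserves that grouping while destroying the
  time trend. Two-sided by $|slope|$, add-one convention.
* *Bootstrap unit*: vessel pairs (cluster bootstrap); all points of a
  resampled pair enter the refit, and the 2.5/97.5 percentiles of the
  refitted slopes form the interval. Points within a pair are not
  exchangeable with points of another pair, so the pair is the natural
  resampling unit.
* Both procedures canonicalise point order internally, so results are
  invariant to row shuffles and bit-reproducible under a fixed seed.

The dispersion-peak estimator averages the treatment-treatment
dissimilarity per time point, smooths with a moving average spanning one
feeding cycle (24 h), and reports the time of the smoothed maximum, with
ties broken to the earliest time.

### Fermentation contrasts

With three vessels per arm, a mixed model has little to work with; the
package instead uses a vessel-level permutation contrast: the effect is
the difference of condition means of per-vessel average responses, and
condition labels are permuted across vessels (the vessel is the
exchangeable unit). At 3v3 this is exact with 20 relabellings and a
two-sided p floor of 0.1; it is a deliberate methodological substitution
for a repeated-measures mixed model, not a reproduction of one.

The propionate:acetate ratio is computed per record and then averaged
within condition (mean of ratios). The ratio of group means is *not*
the same quantity -- for the reference group means, 481.12/1056.99 =
0.455 while the per-sample mean is near 0.48 -- and the per-record form
is what a per-sample assay reports. Percent reduction is
$100(\bar{x}_{ctrl}-\bar{x}_{trt})/\bar{x}_{ctrl}$; note that for total
gas the reference table's quoted "51.8%" is inconsistent with its own
means (which give 48.1%), so the package always reports the formula
value.

## The synthetic-data generator

`synthetic_config()` encodes the emulated study: 3 vessels per condition,
time points 4/12/24 h after feeding on each of 4 days (12 in all),
6467 reads per sample, 120 genera. Counts are Dirichlet-multinomial:
vessel-and-time mean compositions $m_{ct}$, vessel draws
$p \sim \mathrm{Dirichlet}(c_{ct}\, m_{ct})$, counts
$\sim \mathrm{Multinomial}(6467, p)$.

Structure of the mean and dispersion:

* **Base composition**: a fixed log-normal rank-abundance profile
  (log-SD 1.5, a typical steepness for 16S genus profiles) over bulk
  genera assigned to Bacteroidetes/Firmicutes/Proteobacteria and minor
  phyla; five methanogen genera (Methanobrevibacter, Methanosphaera,
  vadinCA11, Methanoplanus, Methanimicrococcus) under Euryarchaeota,
  with >99% of methanogen reads in the first two.
* **Methanogen share**: pinned exactly to `methanogen_baseline` (default
  0.0179, i.e. 1.79%) in control and to $0.0179 \times
  2^{-\text{methanogen\_log2\_depletion}}$ (default exponent 0.4) in
  treatment, with the bulk block renormalised to the remainder. Pinning
  the share exactly makes the generator's Euryarchaeota expectation
  analytic, so parameter-recovery tests have a closed-form target.
* **Dispersion (the Anna-Karenina effect)**: in treatment vessels the
  Dirichlet concentration (default 50) is divided by
  $1 + (\text{akp\_strength}-1)\cdot \text{tent}(t)$, a piecewise-linear
  tent peaking at 72 h (default strength 4). Only the concentration
  moves; the mean composition is untouched, so dispersion effects are
  separable from mean shifts in tests.
* **Shared drift**: Bacteroidetes genera shrink at 0.20/day on the log
  scale in both arms, driving the declining Bacteroidetes:Firmicutes
  ratio that the fermenter system itself induces.
* **Treatment drift**: the 50 rarest bulk genera bloom at 0.80/day (log
  scale) in treatment vessels only, emulating stress-induced opportunist
  blooms. This is what makes treatment-control dissimilarity grow
  roughly monotonically and gives treatment vessels the steeper
  within-vessel time-lag trend. Blooms from the rare tail were chosen
  over symmetric or dominant-genus drift because mass reallocation among
  dominant genera changes community evenness so strongly that it
  interferes with the dispersion signal.
* **Fermentation**: per vessel and time point, CH4, CO2 and six VFAs are
  truncated-at-zero normal draws around the condition means of the
  reference experiment (CH4 12.08 vs 0.59 ml/(g OM), etc.); total gas is
  the sum of the CH4 and CO2 draws, so the component constraint holds by
  construction. Per-record SDs default to $\sqrt{3}\times$ the reported
  pooled SEs of 3-vessel group means, reading the printed SE as
  between-vessel spread. Truncation lifts the realised mean above the
  configured one only where mean/SD is small (the treatment CH4 arm);
  all inference in the package is permutation-based and unaffected.

`synthetic_null_config()` zeroes all three treatment knobs (dispersion
strength, methanogen depletion, treatment drift), making the two arms
exchangeable; it is the basis of the type-I-error calibration tests.

What the generator does *not* model -- and hence what passing tests do
not establish about real data: within-vessel temporal autocorrelation
beyond the mean/dispersion trajectories (time points are conditionally
independent given the trajectory), protozoa or their washout (a 16S
assay does not observe them; the shared drift term stands in
implicitly), mechanistic fermentation chemistry, and sequencing noise
beyond multinomial resampling.

## Numerical and design choices

* Shannon uses the natural log; log-base changes rescale the index.
* Chao1 is the bias-corrected form $S_{obs} + n_1(n_1-1)/(2(n_2+1))$, so
  it is defined when no doubletons are observed.
* Rarefying is true subsampling without replacement (multivariate
  hypergeometric); samples below the target depth are dropped with a
  warning, never padded.
* Unclassified lineage tails are encoded `unclassified_<nearest
  classified parent>`, keeping rank aggregation total.
* Permutation exceedance comparisons use a $10^{-12}$ tolerance so exact
  ties (e.g. in degenerate fixtures) count as exceedances.
* The master seed of a pipeline run fans out to per-stage child seeds by
  a fixed affine map, so any stage can be rerun in isolation; the run
  manifest records the configuration, all child seeds, and the md5 of
  every artifact.
* Degenerate HOMOVA groups (zero internal variance) are guarded with the
  smallest positive double before the log; fixtures exercising $B=0$
  remain exact.

## Problem sizes used by the test suite

The suite is designed for a single CPU: calibration tests use 1000 null
replicates of small communities (12 samples x 40 taxa at depth 500, 199
permutations each); parameter-recovery tests sweep 100 seeds of the
default full-size configuration (72 samples x 120 genera at depth 6467);
oracle-equivalence tests enumerate permutations exhaustively on at most
8 samples. These sizes give each binomial/recovery criterion enough
resolution to fail visibly if the implementation drifts.

## Known limitations

* The percentile cluster bootstrap undercovers with few clusters: in
  design measurements, empirical 95%-CI coverage was roughly 0.87 with 6
  vessel pairs, 0.93 with 30, approaching the nominal level from below
  as clusters grow. This is the textbook behaviour of percentile cluster
  bootstraps. Intervals for a 3-vessels-per-arm design should be read as
  slightly optimistic; the test suite asserts a 0.90 coverage floor at
  30 clusters plus monotone widening in noise.
* AMOVA/HOMOVA assume exchangeability of samples under the null; with
  repeated measures per vessel the per-time-point tests (6 samples each)
  are the cleaner use, and the all-times test should be read
  descriptively.
* No phylogeny-aware metrics (UniFrac) and no BIOM I/O; the exchange
  formats are the mothur-style shared/taxonomy/PHYLIP files.
* The trajectory analysis fits each pair category separately; no pooled
  multi-category regression or changepoint model for the reconvergence
  after the dispersion peak.
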