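---
title: "Inferring community-assembly processes with phyloassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community-assembly processes with phyloassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloassembly)
```

## The question the package answers

Microbial communities are shaped by a mixture of deterministic (niche)
processes — environmental filtering, competitive exclusion — and stochastic
(neutral) processes — dispersal, immigration, ecological drift. Given an OTU
count table, a rooted phylogeny over the OTUs and per-sample metadata,
`phyloassembly` quantifies the relative contribution of five processes to
the turnover between every pair of samples, fits Sloan's neutral community
model, and relates community turnover to environmental and geographic
distance. The design target is a soil-transect study — elevations by soil
layers with replicate cores — but nothing in the machinery is specific to
soil.

## The inference framework

**Phylogenetic nulls.** For a single sample, the mean nearest-taxon distance
(MNTD) measures how phylogenetically clustered its members are. The nearest
taxon index is the sign-flipped standardized effect size,
`NTI = -(MNTD_obs - mean_null) / sd_null`, against a "taxa.labels" null
that shuffles tip labels on the patristic distance matrix across the full
analyzed taxon pool while preserving richness; positive NTI means
clustering, and values above +2 are conventionally read as environmental
filtering. For a pair of samples, beta-MNTD averages, in both directions,
each taxon's distance to its nearest relative in the other sample
(abundance-weighted by default), and beta-NTI is its z-score against the
same label-shuffling null. |beta-NTI| > 2 indicates selection: above +2 the
pair is more phylogenetically different than chance (variable selection),
below -2 more similar (homogeneous selection).

**Raup-Crick on Bray-Curtis.** For pairs not dominated by selection, the
RCbray null asks whether taxonomic turnover exceeds what probabilistic
re-assembly would give: each sample is rebuilt with its observed richness by
drawing taxa with probability proportional to occupancy, filling its
observed reads in proportion to metacommunity relative abundance. RCbray
rescales the percentile of the observed Bray-Curtis within the null to
[-1, 1]; above +0.95 the pair is attributed to dispersal limitation, below
-0.95 to homogenizing dispersal, and otherwise to drift ("undominated").
Threshold values themselves (|beta-NTI| = 2, |RC| = 0.95) fall on the
stochastic/undominated side: only values *exceeding* a threshold signal a
dominant process. Together the two nulls partition all pairs into five
processes; `partition_fractions()` aggregates percentages within sample
groups (soil layer, elevation band, or any metadata column).

**Sloan's neutral model.** Across samples, a taxon's detection frequency is
predicted from its metacommunity mean relative abundance `p` by
`Beta(N m p, N m (1 - p))`, where `N` is the community size (mean reads per
sample) and `m` the migration rate — the probability that a death is
replaced by an immigrant. `fit_ncm()` estimates `m` by one-parameter
nonlinear least squares and reports the generalized
`R^2 = 1 - SS_res / SS_tot` (values above ~0.2 are conventionally read as a
substantial neutral contribution; R^2 can be negative for fits worse than a
constant). Taxa above/below the 95% band around the prediction (Wilson
score intervals by default, Clopper-Pearson behind `ci = "exact"`) are
candidates for positive/negative selection.

*Detection threshold.* A taxon at relative abundance `x` is missed by `N`
reads with probability `(1 - x)^N`, so the step-function detection
threshold that matches read-sampled data is `d = 1 - 2^(-1/N)` (about
`ln 2 / N`), the 50%-detection point. This is the package default. The
simpler reciprocal-depth convention `d = 1/N` is available by passing `d`
explicitly; on read-sampled data it systematically inflates the fitted
migration rate (the package's generator makes this visible: with true
`m = 0.5` the `1/N` fit converges near 0.73 even with exact frequencies,
while the default recovers `m` to within a few percent).

**Species-abundance distribution.** `fit_lognormal_sad()` bins pooled
per-taxon abundances into Preston doubling octaves — octave k holds
abundances in `(2^(k-1), 2^k]`, counts on an exact power of 2 split half
into each adjacent octave, mirroring `vegan::as.preston(tiesplit = TRUE)` —
and fits `S(R) = S0 exp(-a^2 R^2)` with `R` the signed offset from the
modal octave. As an AIC comparator on the same octaves with the same
parameter count and the same Gaussian-residual AIC
(`n log(SS_res / n) + 2k`), a geometric-series-shaped exponential decline
`S(j) = A exp(-b j)` is fitted; only the AIC difference between the two
fits is meaningful, not either AIC in isolation.

**Distance correlations.** `env_distance()` z-scores each environmental
variable and takes Euclidean distances; `geo_distance()` defaults to
haversine great-circle km on a 6371-km sphere (a `euclidean_degrees` mode
exists for comparability with analyses that use raw coordinates).
`mantel_test()` / `partial_mantel_test()` wrap vegan's permutation Mantel
machinery; the default alternative is one-sided "greater", the
distance-decay convention, with a two-sided option computed from the
permutation distribution of |r|. Permutation p-values use the add-one rule
and are never zero. A partial Mantel whose control matrix is exactly
collinear with the second matrix is undefined and returned as `NA` with a
warning rather than a number.

## Null-model implementation choices

* One tip-label shuffle per replicate is shared by all sample pairs (for
  both beta-NTI and the RCbray assemblies). Pairwise values are then
  mutually consistent, the computation vectorizes, and results remain valid
  per pair; the alternative — independent shuffles per pair — differs only
  in the correlation structure between pairs.
* Defaults are 999 randomizations for beta-NTI and RCbray and 1000 for NTI,
  with 9999 Mantel and 999 partial-Mantel permutations — the counts
  conventional in this literature. All are arguments.
* Ties in the RCbray empirical CDF count at half weight (mid-P), with a
  1e-10 tolerance for floating-point equality of Bray-Curtis values.
* Degenerate nulls (`sd_null = 0`, e.g. a star tree with equal branch
  lengths) yield `NA`, a warning and an `n_undefined` count; downstream
  percentage summaries exclude and report them. They are never silently 0.
* beta-MNTD's abundance-weighted form coincides exactly with
  `picante::comdistnt(abundance.weighted = TRUE)`. The unweighted form is
  the mean of the two directional means; `comdistnt`'s unweighted variant
  instead pools nearest-taxon distances over both communities before
  averaging, so the two differ when richness differs between the samples.

## The synthetic-data module

No public dataset accompanies the motivating study design, so validation
rests on generators whose assembly regime is known:

* `simulate_tree()` — pure-birth (Yule) phylogeny, unit birth rate.
* `simulate_metacommunity()` — log-normal relative abundances,
  `sad_sigma = 1.5` by default. This is a realistically broad spread for
  soil fungi while keeping single-taxon dominance moderate; with much
  larger spreads one or two taxa can carry most of the reads, and any
  occupancy-based null becomes dominated by whether those few taxa are
  drawn, degrading the identifiability of every regime.
* `simulate_neutral_table()` — per sample, composition ~
  Dirichlet(`Nm * p`), reads multinomial: exactly the stationary local
  community Sloan's model assumes, so `fit_ncm()` should recover
  `m = Nm / reads`. This is deliberately a stationary-form generator, not a
  birth-death-immigration time-stepper.
* `simulate_selection_table()` — a Brownian-motion trait on the tree (so
  filtering is phylogenetically autocorrelated, which a phylogenetic
  statistic requires to register selection), Gaussian niche filter of
  width `sigma_w` around a per-sample optimum, multinomial reads.
  Contrasting optima between sample groups produce variable selection;
  a shared optimum produces homogeneous selection. For homogeneous
  selection to be *detectable* the shared optimum must sit in the tail of
  the trait distribution (clades, not a polyphyletic mid-trait band, pass
  the filter) and the analyzed pool must retain the unselected taxa.
* `simulate_dispersal_limited_table()` — taxa assigned at random (no
  phylogenetic structure) to patch pools sharing a fraction `overlap`;
  samples draw only from their patch. This yields |beta-NTI| < 2 with
  RCbray near +1 between patches — the dispersal-limitation signature.
* `simulate_metadata()` — a 7-elevation (889-3837 m) x 3-layer x
  3-replicate design with soil chemistry responding smoothly to elevation
  and depth plus noise.

Scenario defaults (63 samples, 66,000 reads per sample, ~1000 taxa) mirror
a realistic amplicon study; tests and the acceptance script run scaled-down
instances (hundreds of taxa, 10-30 samples, ~2000 reads, 199
randomizations), sizes chosen so the whole validation suite runs on a
laptop while every statistic stays identifiable. Generators are pure
functions of their seed, and the pipeline derives per-stage seeds from one
global seed by stable stage names, so adding a stage never perturbs another
stage's randomness and identical configs give byte-identical outputs.

What the generators do *not* emulate: PCR and primer bias, chimeras,
sequencing error, compositional zero-inflation beyond multinomial sampling,
spatially explicit landscapes, or time-resolved dynamics. Passing the
validation suite therefore shows the estimators are correct under the
models they assume, not that those models capture every feature of real
amplicon data.

## Worked example

```{r example, eval = FALSE}
sc <- simulate_scenario("neutral", n_taxa = 300, n_samples = 30,
                        reads = 2000, seed = 1)
bn <- beta_nti(sc$counts, sc$tree, n_null = 199, seed = 2)
rc <- raup_crick_bray(sc$counts, n_null = 199, seed = 3)
partition_fractions(bn, rc)$summary
fit_ncm(sc$counts)
```

Or end-to-end, writing TSV/JSON outputs and a manifest:

```{r pipeline, eval = FALSE}
cfg <- default_config(out_dir = "run1", seed = 1)
cfg$simulate <- list(regime = "neutral", n_taxa = 300, n_samples = 30,
                     reads = 2000)
cfg$nullmodels$n_null <- 199
report <- run_pipeline(cfg)
```

## Numerical and edge-case behavior

* Counts must be non-negative integers; zero-total samples are an error
  naming the sample. Taxa in the table but absent from the tree are dropped
  by `align_inputs()` with a logged count (ITS OTU tables routinely exceed
  their reference tree); orderings are lexicographic so outputs are
  byte-stable.
* Chao1 uses the classic `SR + F1^2 / (2 F2)` with the bias-corrected form
  only when no doubletons exist; ACE uses the standard rare-threshold-10
  estimator and falls back to `SR` when no rare class exists. Shannon is in
  nats; "Simpson" is Gini-Simpson `1 - sum(p^2)`.
* Bray-Curtis and weighted UniFrac operate on relative abundances, removing
  library-size artifacts; no rarefaction is applied by default (a
  `rarefy` flag exists in `alpha_diversity()`).
* The migration-rate search is bounded to (1e-6, 1] and solved by Brent
  optimization of the least-squares objective (one parameter, so this is
  exact NLS); octave-curve fits use Levenberg-Marquardt with the modal
  octave fixed as the mode of the fitted Gaussian.
* All acceptance-grade checks are reproduced by `scripts/acceptance.R` and
  the test suite; the vignette states no number they do not compute.

## Known limitations

* The five-process partition inherits the thresholds' arbitrariness
  (|z| = 2, |RC| = 0.95); fractions shift smoothly with the thresholds and
  should be read comparatively, not absolutely.
* Beta-NTI power depends on how the analyzed taxon pool is framed: if only
  taxa passing a shared filter are ever observed, homogeneous selection is
  invisible to a within-pool null.
* The neutral fit assumes one well-mixed metacommunity; strong group
  structure should be handled with `ncm_per_group()`.
* Incidence-based Raup-Crick, alternative null algorithms (independent
  swap, quasiswap), generalized UniFrac and ordination are out of scope.
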