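# phyloassembly

Community-assembly inference for microbial ecology in R. Given an OTU count
table (taxa × samples, TSV), a rooted Newick phylogeny and per-sample
metadata, the package quantifies how much of the turnover between
communities is driven by deterministic processes (variable / homogeneous
selection) versus stochastic ones (dispersal limitation, homogenizing
dispersal, ecological drift), and how compatible the community is with
neutral assembly. It was built for altitudinal soil-transect designs
(elevations × soil layers × replicate cores) but applies to any
sample-by-taxon survey with a phylogeny.

## What it computes

- **α-diversity** per sample: species richness, Chao1, ACE, Shannon (nats),
  Gini–Simpson, Faith's PD, MNTD and the nearest taxon index
  NTI = −(MNTD_obs − mean_null)/sd_null under a richness-preserving
  tip-label-shuffling null.
- **β-diversity**: Bray–Curtis, weighted (optionally normalized) UniFrac,
  and abundance-weighted βMNTD.
- **Phylogenetic null models**: βNTI = (βMNTD_obs − mean_null)/sd_null over
  999 tip-label randomizations, and the Bray–Curtis Raup–Crick null
  (RCbray ∈ [−1, 1]) from probabilistic community re-assembly
  (occupancy-weighted draws, abundance-proportional fills).
- **Five-process partition** per sample pair: βNTI > 2 → variable
  selection; βNTI < −2 → homogeneous selection; otherwise RC > 0.95 →
  dispersal limitation, RC < −0.95 → homogenizing dispersal, else
  undominated (drift); aggregated as percentages within sample groups.
- **Sloan's neutral community model**: occurrence frequency vs mean
  relative abundance, `f̂ = 1 − BetaCDF(d; N m p, N m (1−p))`, fitted for
  the migration rate m with generalized R², plus per-OTU
  above/neutral/below partition at the 95% band.
- **Preston log-normal SAD**: octave binning with tie splitting, fit of
  `S(R) = S0·exp(−a²R²)`, AIC contrast against a geometric-series
  comparator.
- **Mantel / partial Mantel** tests of community distances against
  standardized environmental distances and haversine geographic distances.
- **Synthetic generators** with known assembly regimes (neutral
  Dirichlet–multinomial, Brownian-trait selection, patch-limited
  dispersal) that serve as ground truth for the whole pipeline.

## Worked example

```r
library(phyloassembly)

sc <- simulate_scenario("neutral", n_taxa = 300, n_samples = 30,
                        reads = 2000, seed = 1)
bn <- beta_nti(sc$counts, sc$tree, n_null = 199, seed = 2)
rc <- raup_crick_bray(sc$counts, n_null = 199, seed = 3)
round(partition_fractions(bn, rc)$summary$stochastic_pct, 1)
#> [1] 96.1
fit_ncm(sc$counts)
#> Sloan neutral community model fit
#>   m = 0.1057, R2 = 0.9186, N = 2000.0, d = 3.47e-04, samples = 30
#>   taxa partition: above=29, below=11, neutral=248
```

The data were simulated under neutral immigration with migration rate
m = 0.1, and the pipeline reads them back correctly: 96.1% of sample pairs
fall in the stochastic band (|βNTI| < 2), the fitted migration rate is
0.106, and the neutral model explains 92% of the variance in occurrence
frequency. On real data, replace the simulate block with
`read_count_table()`, `read_tree()`, `read_metadata()` and
`align_inputs()`, or run everything from one config:

```r
cfg <- default_config(out_dir = "run1", seed = 1)
cfg$input <- list(table = "otu.tsv", tree = "tree.nwk",
                  metadata = "meta.tsv")
report <- run_pipeline(cfg)   # writes TSV/JSON outputs plus a manifest
```

A thin command-line wrapper lives at `inst/cli/phyloassembly.R`
(subcommands `simulate` and `run`).

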