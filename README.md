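# meconet

Molecular ecological network inference for soil microbiome surveys
that pair 16S amplicon (OTU) count tables with functional gene array
(GeoChip-style) signal intensities.

Soil studies of this kind ask two linked questions: which taxa
co-occur strongly enough to suggest ecological interaction, and which
taxa associate with which functional gene categories. Both are
network-inference problems on awkward data — compositional counts,
noisy array signals, and far more feature pairs than samples — and
both have field-standard answers that this package implements as
tested, reusable functions:

* **RMT-thresholded co-occurrence networks (pMENs).** The similarity
  threshold is not hand-picked: the spectrum of the thresholded
  correlation matrix is unfolded and its nearest-neighbour spacing
  distribution (NNSD) is tested against the Wigner surmise
  (GOE noise, level repulsion) and the Poisson law *P(s) = e^-s*
  (uncorrelated modular signal). The chosen threshold is the smallest
  at which the NNSD becomes Poisson-consistent and Wigner-inconsistent.
  Modules come from greedy modularity maximisation; nodes are classed
  as module hubs, network hubs, connectors or peripherals from the
  within-module degree z-score *Z_i* and participation coefficient
  *P_i = 1 − Σ_m (k_im/k_i)²* with the standard cutoffs 2.5 / 0.62.
* **Ensemble taxa–function association networks.** Four measures per
  pair (Pearson, Spearman, Bray–Curtis, symmetrised Kullback–Leibler),
  a ReBoot null (permute each feature on the raw abundance scale,
  re-close each sample's composition, re-measure) that absorbs
  compositionality-induced correlation, bootstrap stability, and
  Brown's method to combine the four dependent p-values
  (moment-matched scaled chi-square on *X = −2 Σ ln p*; exactly
  Fisher's method under independence). Edges need ≥ 2 supporting
  measures, |r| > 0.8, and combined p < 0.05.
* **Preprocessing and summaries** as practised for such data:
  rarefaction, minimum-occurrence filtering, array signal-to-noise
  filtering, lnMR normalisation (ln(x+1) over mean total intensity),
  Shannon / Simpson / inverse-Simpson / evenness indices, and
  shared/endemic gene-set overlap between sample groups.
* **A synthetic generator** that emulates a 3 soil types × 4 depth
  layers × 2 growth stages × 2 replicates mesocosm design with planted
  correlation modules and taxa–function couplings, so every stage has
  a ground-truth recovery test.

## Worked example

Simulate a survey with three planted co-occurrence modules and ten
taxa–function couplings, preprocess, and run both network stages:

```r
library(meconet)

cfg <- synthetic_config(n_taxa = 30, n_modules = 3, within_module_rho = 0.8,
                        coupling_strength = 0.9, seed = 42)
sim <- simulate_dataset(cfg)

otu <- rarefy(sim$otu, 8000, seed = 1)
otu <- prevalence_filter(otu, min_occurrence = 4)
head(alpha_diversity(otu), 3)
#>           sample_id observed  shannon gini_simpson inverse_simpson simpson_evenness
#> 1 soil1.A.stage1.R1       30 2.952759    0.9227427        12.94376        0.4314588
#> 2 soil1.A.stage1.R2       30 2.755539    0.9109989        11.23582        0.3745274
#> 3 soil1.A.stage2.R1       30 3.153339    0.9469939        18.86576        0.6288585

cm   <- correlation_matrix(otu)
scan <- rmt_threshold(cm)
scan
#> RMT threshold scan over 70 candidates
#>   GOE-to-Poisson transition at threshold 0.68

net   <- build_network(cm, scan$chosen_threshold)
mem   <- detect_modules(net)
roles <- node_roles(net, mem)
summarize_pmen(net, mem, roles, scan$chosen_threshold)
#>   threshold network_size total_links n_module_hubs pct_positive pct_negative
#> 1      0.68           29          81             0          100            0
#>       avgK modularity
#> 1 5.586207  0.6310014

gcn   <- lnmr_normalize(sim$geochip)
edges <- filter_edges(ensemble_edges(otu, gcn, n_perm = 50, n_boot = 50, seed = 2))
sum(edges$retained)
#> [1] 10          # exactly the ten planted couplings, out of 600 tested pairs
build_bipartite(edges)$summary
#>   n_nodes n_edges average_degree modularity
#> 1      20      10            0.5        0.9
```

Reading the output: the scan places the similarity threshold at 0.68 —
above the band of sampling/compositional noise correlations, below the
planted within-module correlations — and the resulting 29-node network
has mean degree `avgK = 2L/N ≈ 5.59` and modularity 0.63 over the three
planted modules. The ensemble stage retains 10 of 600 taxon–category
pairs, exactly the planted couplings; the bipartite summary reports the
edges-per-node convention (`n_edges/n_nodes = 0.5`) used for
taxa–function tables, as opposed to the `2L/N` convention used for
co-occurrence networks (both are exposed via `avg_connectivity()`).

`run_pipeline()` chains simulate → preprocess → diversity → pmen →
conet from a single YAML or list config, writes TSV/GraphML outputs,
and records a manifest with per-file checksums and per-stage seeds.

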