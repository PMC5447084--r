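---
title: "Co-occurrence and taxa-function network inference for soil microbiome surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence and taxa-function network inference for soil microbiome surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`meconet` implements the network half of a combined amplicon +
functional-gene-array analysis of soil microbial communities: the
preprocessing steps such data need (rarefaction, prevalence filtering,
array signal-to-noise filtering, lnMR normalisation), alpha-diversity
and gene-set overlap summaries, random-matrix-theory (RMT) thresholded
co-occurrence networks with Zi-Pi node-role classification, and a
CoNet-style ensemble of four association measures with a ReBoot
permutation-renormalisation null and Brown's method for combining the
dependent per-measure p-values. Because raw data of the motivating kind
of study (mesocosm soil profiles assayed by 16S sequencing and a
functional gene array) are rarely deposited, the package ships a
synthetic generator that emulates the study design with planted,
recoverable structure; every stage of the pipeline is validated against
that ground truth.

# The synthetic generator

The generator emulates a factorial mesocosm survey: 3 soil types x 4
depth layers x 2 growth stages x 2 replicate columns = 48 samples by
default. Taxon abundances follow a log-normal latent field: an
`n_taxa`-dimensional Gaussian whose correlation matrix is block
structured -- `within_module_rho` (default 0.7) inside each of
`n_modules` contiguous taxon blocks, `cross_module_rho` (default 0)
between blocks. If the requested block matrix is not positive
semi-definite it is repaired by repeatedly shrinking all off-diagonal
entries by 5%, a monotone and reproducible rule. Counts are multinomial
draws of `sequencing_depth` reads per sample (default 10,000 -- deep
enough that sampling noise does not mask planted structure, small
enough to keep simulation-heavy tests fast) with probabilities
proportional to `exp(latent)`. This deliberately induces the closed-sum
(compositional) distortion of real amplicon tables: the ensemble
module's ReBoot null exists precisely to correct compositionality, so
the generator must produce it.

Functional-gene-array signals are Gaussian background noise
(`background_mean` 1000, `background_sd` 200, scanner-intensity scale)
except for coupled categories, whose signal is an affine function of a
chosen taxon's standardised latent *relative* abundance with planted
correlation `coupling_strength`. The relative-abundance scale (rather
than the log-latent scale) is used because it is the scale on which
the downstream association measures operate, so a planted coupling of
0.9 surfaces to the measures at about 0.9. Negative synthetic signals
are clipped at zero, as scanner intensities are non-negative. An
optional per-layer shift of latent means for a configurable taxon
subset reproduces surface- versus depth-enriched abundance contrasts
qualitatively.

What the generator does *not* emulate: read-level errors and chimeras,
taxonomy misassignment, overdispersion beyond the log-normal latent,
probe-level cross-hybridisation, and genuinely sparse rare-taxon
tails. Tests passing on this generator therefore demonstrate that the
algorithms recover the structure they claim to recover under a clean
compositional model, not that real soil data will be as forgiving.

# Preprocessing

* `rarefy()` subsamples each sample without replacement (multivariate
  hypergeometric) to a common depth. Each sample draws from its own
  RNG substream derived from `(seed, sample id)`, so results do not
  depend on column order.
* `prevalence_filter()` keeps features observed in at least
  `min_occurrence` samples (default 4) of the sample group passed in --
  occurrence is meant to be evaluated within the group (e.g. one depth
  layer) whose network is being built.
* `snr_filter()` computes SNR = (signal - background mean) / background
  sd and removes probes *below* the threshold (default 2); a probe
  exactly at the threshold survives.
* `lnmr_normalize()` maps every array value x to ln(x+1)/M. The wording
  of lnMR in the literature is ambiguous about M; the default takes M
  as the global mean of per-sample total intensities, which leaves
  samples comparable, and a `per_sample = TRUE` variant divides by each
  sample's own total instead. Both are provided rather than guessing
  intent. Note the global divisor is a single scalar, so lnMR does not
  close samples to a common sum -- lnMR-normalised tables are *not*
  compositional, which matters for the ensemble module below.

# RMT-thresholded co-occurrence networks

The similarity matrix is the Pearson correlation across samples of
ln(relative abundance + pseudocount) (the transform is configurable;
the pseudocount defaults to half the smallest nonzero relative
abundance). The threshold at which correlations become "real" is chosen
by random matrix theory: for each candidate threshold s in a grid
(default 0.30-0.99 by 0.01, matching the 2-decimal convention of
published threshold tables), correlations below s are zeroed, the
non-isolated submatrix's eigenvalues are computed, the spectrum is
unfolded, and the nearest-neighbour spacing distribution (NNSD) is
tested by chi-square against the Poisson law exp(-s) and the Wigner
surmise. The chosen threshold is the smallest candidate whose NNSD is
consistent with Poisson (p > 0.05) and inconsistent with Wigner -- the
point where GOE-like noise correlations have been pruned and only
modular signal remains.

Numerical choices:

* Unfolding fits a cubic smoothing spline (default 10 effective
  degrees of freedom, capped by the spectrum size) to the empirical
  cumulative spectral function, maps eigenvalues through the fit, and
  rescales the increments to mean exactly one. Exact duplicate
  eigenvalues are collapsed first, as usual for degenerate spectra;
  candidate thresholds whose network has fewer than 20 eigenvalues are
  recorded but skipped.
* The chi-square tests use equal-probability bins with expected count
  at least 5 (the classical applicability condition).
* Edges are thresholded on |r| but keep their sign, so summaries can
  report positive/negative link percentages next to a single
  threshold.

Modules come from igraph's fast-greedy modularity maximisation on
absolute edge weights. One tie rule is added: when splitting a
connected component gains no modularity over leaving it whole (greedy
implementations can cut at numerically-zero-Q ties on, e.g., complete
graphs), the component is kept as a single module. Modularity Q is
Newman-Girvan, computed on the unweighted graph by default.

Node roles use the within-module degree z-score Zi and participation
coefficient Pi with the standard cutoffs (module hub: Zi > 2.5, Pi <
0.62; network hub: Zi > 2.5, Pi > 0.62; connector: Zi < 2.5, Pi >
0.62; peripheral otherwise). Degenerate modules (size one, or zero
spread of within-module degree) get Zi = 0 rather than an infinity,
and boundary values fall to the non-hub/non-connector side.

Two printed conventions for average connectivity coexist and both are
implemented explicitly: `avg_connectivity(n, l, "pmen")` = 2L/N (mean
node degree, used in pMEN topology tables) and `"mutualistic"` = L/N
(edges per node, used in bipartite taxa-function tables).

# Ensemble taxa-function association inference

For every taxon-category pair (or within-table pair), four measures
are computed: Pearson and Spearman correlation, Bray-Curtis
dissimilarity, and symmetrised Kullback-Leibler divergence on
per-feature distributions with pseudocount 1/total. Count tables are
closed to relative abundance before measuring; lnMR-normalised array
tables are used as-is, because their global divisor leaves them
non-compositional (closing a small synthetic category panel to unit
sum would manufacture distortion that real arrays, with thousands of
probes, do not have).

The null model is ReBoot: each permutation shuffles both features
across samples *on the raw abundance scale*, re-embeds the shuffled
values in each sample's remaining composition, re-closes the column,
and recomputes the measure. The raw scale is essential: permuting
already-closed fractions carries each value's source-sample
denominator into the target sample, and the null then fails to
reproduce the very correlation that closure induces -- the correction
the procedure exists to make. Non-compositional sides get a plain
permutation null. All four measures share one permutation stream per
feature, which is what lets the dependence between their p-values be
estimated rather than assumed.

Per-measure p-values are two-sided z-scores of the observed measure
against the null mean and standard deviation, floored at 1/(n_perm+1)
(nothing can look more extreme than the resolution of the null). A
bootstrap over samples (default 100 resamples) supplies a stability
condition: a measure only counts towards an edge's `support` if its
central 95% bootstrap interval excludes the null mean. Stability is
deliberately a condition on support, not an overwrite of the p-value:
forcing unstable p-values to 1 would destroy the uniform-under-null
marginals that Brown's combination assumes, and it is the bootstrap --
not the z-test -- that correctly rejects near-degenerate associations
whose observed value sits microscopically but systematically above a
tight null.

Brown's method combines the four dependent p-values: X = -2 sum ln p
is referred to a scaled chi-square whose scale and degrees of freedom
are moment-matched using the empirical covariance of -2 ln p across
the shared permutation stream. With zero covariance this is exactly
Fisher's method (a tested invariant).

An edge is retained when it has support from at least 2 measures, the
larger absolute correlation (Pearson or Spearman -- a "coefficient"
cutoff is not meaningful for unbounded divergences) exceeds 0.8, and
the combined p is below 0.05. A Benjamini-Hochberg adjustment across
pairs is available behind `fdr = TRUE` but is off by default: the
permutation floor bounds how small a combined p can get (about 2e-3 at
100 permutations), and stacking BH across hundreds of pairs on top of
that floor leaves the filter unable to retain any edge at practical
permutation counts, regardless of effect size.

# Problem sizes used in validation

The packaged tests exercise the pipeline at sizes chosen to make the
planted structure statistically unambiguous while keeping the suite
quick: two-block recovery uses 30 taxa x 500 samples at depth 20,000
over ten seeds; ensemble calibration uses 200 replicates of
independent 20-taxa x 10-category tables at 48 samples with 50
permutations and 50 bootstraps; power uses ten replicates with
couplings planted at 0.9. `scripts/acceptance.R` re-runs scaled
versions of the same experiments from scratch.

# Known limitations

* The RMT scan assumes enough non-isolated features (>= 20) at a
  candidate threshold; very small panels cannot be scanned and need an
  explicit threshold.
* On data whose cross-feature noise correlations are essentially zero
  (e.g. very large sample sizes), every candidate threshold above the
  noise floor yields a Poisson-consistent spectrum and the scan
  legitimately returns the smallest candidate; the threshold is then a
  lower bound rather than a transition point.
* Greedy modularity is a heuristic; on small graphs it is verified
  against exhaustive search to within 0.05 in Q, but it can split or
  merge weakly separated modules.
* Bray-Curtis carries no signal between features on very different
  scales (its permutation null is then nearly a point mass); the
  support rule handles this honestly (the measure simply cannot vote),
  but it means `support` rarely reaches 4 in bipartite mode.
* The pipeline treats the gene-category panel as given; probe-to-gene
  curation and dye-bias correction are out of scope.
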