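---
title: "Models and design choices in micronorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in micronorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`micronorm` is a benchmarking toolkit: it implements the normalization
strategies and two-group differential abundance tests commonly applied to
microbiome count tables, together with simulation designs whose ground truth
is recorded, so that sensitivity, false discovery rate (FDR) and type-I
error of any (normalization, test) pipeline can be measured. This vignette
documents the models, the tunable parameters, and the places where the
design was genuinely open and a choice had to be made.

## The data and its three nuisances

A count table holds non-negative integers, taxa in rows and samples in
columns. The column sum (library size) is an artifact of sequencing effort,
not biology; tables are typically ~90% zeros; and because a specimen only
ever reveals *relative* abundances, the data are compositional: if 10% of
taxa genuinely increase in one ecosystem, the relative abundance of every
other taxon mechanically decreases after renormalization. The package's
simulations are built to separate these three effects.

## Normalization

All scaling methods rescale to a common "counts" scale through
C = median library size of the input table, so outputs of different methods
are comparable.

* **Proportions** divide each column by its sum.
* **Rarefying** draws exactly `depth` reads per sample without replacement
  (multivariate hypergeometric); samples shallower than the depth are
  excluded and reported, because downstream accuracy scoring may want to
  count them as errors. A multinomial (with-replacement) variant exists for
  reproducing older studies.
* **log upper quartile** scales each sample by the 75th percentile of its
  *nonzero* counts before the log2 transform. On ~90%-sparse data the raw
  75th percentile is 0 for most samples, which would be degenerate; the
  nonzero-only convention is recorded in the output parameters.
* **CSS** scales each sample by the cumulative sum of its counts up to a
  quantile of its own count distribution. The quantile is chosen adaptively:
  per-sample quantile curves of the nonzero counts are computed on the grid
  0.01–0.99, the reference is their across-sample median curve, and the
  chosen point is the first grid value where the median relative deviation
  of the sample curves from the reference exceeds its running minimum by
  more than 10%, subject to a 2% floor so that integer quantization at low
  quantiles (where deviations are exactly zero) cannot trigger it. If no
  such point exists the method falls back to the median (0.5) with a
  warning. The defining property ("scale only the segment of the
  distribution that is relatively invariant across samples") names a goal,
  not an estimator, so the estimator above is this package's rendering and
  its chosen quantile is always recorded.
* **Size factors + variance stabilization.** Size factors are the classical
  median-of-ratios: the median over taxa of counts divided by the taxon's
  geometric mean, rescaled to geometric mean 1. Only taxa positive in every
  sample enter; if none exists a pseudocount of 1 is added (recorded). A
  single NB dispersion α is then estimated by moments (median of
  (v−m)/m²) and the closed-form transform
  f(x) = log2(1 + 2αx + 2√(αx(1+αx))) − log2(4α) is applied; f is the
  integral of (μ + αμ²)^(−1/2) rescaled so that f(x) − log2(x) → 0 at large
  x. For α ≤ 1/4, f(0) < 0: with the default `clamp_negatives = TRUE`
  negative values are set to zero, which deliberately zeroes rare taxa (and
  is why this normalization degrades presence/absence metrics). When the
  moment estimate of α is non-positive the Poisson-limit log2(x+1) is used
  with a warning.
* **TMM** computes, against a reference sample (the one whose upper
  quartile/library-size ratio is closest to the across-sample mean), the
  precision-weighted mean of per-taxon log2 ratios after trimming 30% of
  the M-values and 5% of the A-values (the method's canonical defaults,
  exposed as parameters); the factor is 2 to that mean, rescaled to
  geometric mean 1.

## Distances, ordination, clustering, PERMANOVA

Euclidean, Bray-Curtis and binary Jaccard come from `vegan::vegdist`;
unweighted and weighted UniFrac from `phyloseq::UniFrac`, the weighted
variant normalized to [0, 1] so metrics are comparable in ordination.
Presence for binary metrics means value > 0 *after* normalization. PCoA is
the Gower-centered eigendecomposition (`cmdscale`); negative eigenvalues
are reported, never corrected. PAM clustering is `cluster::pam`
(deterministic BUILD + SWAP) plus seeded random restarts, keeping the
solution with the lowest total within-cluster distance. Clustering accuracy
is maximized over the matching of cluster labels to group labels; with
`penalize_dropped = TRUE` the samples removed before clustering (e.g. by
rarefying) enter the denominator as errors — with a rarefaction depth at
the 15th percentile of 40 library sizes this caps a perfect clustering at
34/40 = 85%, which is why the package also offers the unpenalized score.
PERMANOVA is `vegan::adonis2` with sequential (type-I) sums of squares, so
a `library_size` term placed before `group` absorbs depth effects before
biology is assessed; p-values use the (b+1)/(m+1) permutation estimator.

## Differential abundance tests

All tests return per-taxon statistics, raw p, BH-adjusted q, and the set
called at `alpha` (default 0.05). Taxa whose p is undefined (all-zero,
non-convergent) are excluded from the BH ranking rather than imputed.

* **Welch t / Mann-Whitney** are vectorized over taxa; MW uses exact
  p-values when both groups have ≤ 8 samples and the normal approximation
  with mid-rank tie correction otherwise; all-tied taxa get p = 1.
* **NB GLM.** Per-taxon dispersions are method-of-moments estimates on
  size-factor-normalized counts, moderated on the log scale toward a lowess
  mean-dispersion trend with weight `dispersion_shrink` (default 0.5; the
  weight is the knob that trades the conservatism of trend-only dispersions
  against taxon-wise ones). *Wald mode* fits a log-link NB GLM with a group
  covariate and log size-factor offsets. The Wald statistic is the
  maximum-likelihood coefficient over its standard error, referred to a t
  distribution with n−2 degrees of freedom (a small-sample calibration
  choice; the normal reference is anti-conservative at typical group
  sizes). The zero-centered normal prior — variance estimated as
  mean(β²) − mean(se²), floored — shrinks only the *reported* log2 fold
  change. Testing the shrunk coefficient against its posterior spread was
  rejected as a design: under a global null the estimated prior variance
  collapses and the test's size drops to zero, which would make the test
  uninterpretable as a hypothesis test. *Exact mode* conditions the split
  of the (size-factor-adjusted, rounded) group sums on their total under
  NB with the fitted dispersion, summing the probabilities of splits no
  more likely than the observed one over a 1e-12-truncated support window.
* **voom-style moderated t.** log2 counts-per-million with TMM effective
  library sizes and offset 0.5; lowess of √(residual sd) on mean log-count;
  weights are the predicted sd at each fitted value to the power −4;
  weighted least squares per taxon; empirical-Bayes variance moderation by
  closed-form moments matching on log sample variances (the prior df comes
  from a Newton inversion of the trigamma function).
* **Zero-inflated Gaussian.** Each log-scale value (by default log2 of
  CSS-normalized counts + 1) is a mixture of a point mass at zero and a
  Gaussian with intercept + group mean structure; only observations whose
  *count* is zero can carry zero-mass responsibility. In `zig` mode the
  zero-mass probability is a logistic function of log library size shared
  across taxa — the exact reason the model is misled when counts are
  rarefied and the original depths erased (running it on rarefied input is
  allowed but warns). In `zi_lognormal` mode the zero-mass probability is
  taxon-specific with a closed-form M-step. Both M-steps maximize the
  complete-data likelihood exactly, so the observed-data log-likelihood is
  provably non-decreasing; the trace is recorded and a decrease beyond
  numerical slack aborts with diagnostics. The group effect is tested with
  the same moments-matched moderated t, weights 1 − responsibility.
* **ANCOM.** For each ordered pair (i, j) the per-sample log-ratio
  log((k_i + 0.001)/(k_j + 0.001)) is compared between groups by
  Mann-Whitney (vectorized normal approximation with tie correction; pairs
  are processed in memory-bounded chunks). Per taxon, its m−1 p-values are
  BH-corrected at `alpha` and W counts the rejections — the BH scope is
  within each taxon's m−1 tests, the literal reading of the procedure. Two
  final decision rules are provided and recorded: `threshold`
  (W ≥ 0.7·(m−1), common practice) and `empirical` (cutoff at the largest
  gap between consecutive sorted W values within the top 30%), both
  approximations since the procedure's cutoff construction is not fully
  specified anywhere. The pseudocount is added to *all* counts so that
  within-taxon orderings are preserved. `min_prevalence` (default 0)
  optionally removes taxa observed in fewer than that fraction of samples
  before the analysis: a reference taxon that is zero in most samples is
  censored — its pseudocounted ratio to taxon i just mirrors taxon i's own
  relative abundance — so on very sparse tables the unfiltered procedure
  degenerates toward a relative-abundance test. The package's compositional
  evaluation suite runs ANCOM at `min_prevalence = 0.5` (references must be
  predominantly observed), and the filtered taxa are reported with W = NA.

## Simulation designs

`make_synthetic_template()` draws taxon proportions from a log-normal law
whose log-sd is calibrated by root finding — deterministically, given the
seed — so that multinomial sampling at depth 2000 is expected to produce
the requested zero fraction (default 0.9). This emulates two features of
real survey tables: heavy-tailed rank-abundance curves and ~90% sparsity.
It does **not** emulate taxon-taxon correlation structure, phylogenetic
signal, sequencing error, or batch effects, so pipelines passing these
suites are validated against the stated nuisances (depth variation,
sparsity, compositionality) and nothing more.

Library sizes are drawn log-normally around the median `N_L` with log-sd
`spread` (default 0.5, putting ~95% of samples within a ~7× range); the
spread of real per-sample depths around their median is study-specific, so
it is a recorded parameter, not a constant.

* **Clustering design:** two templates are mixed as
  normalize(ES·π_A + π_B) versus normalize(ES·π_B + π_A); ES = 1 makes the
  classes identical and large ES recovers the pure templates. Samples are
  multinomial, 40 per set by default, with the depth grid
  1000/2000/5000/10000 supported.
* **Balanced design:** the true-positive set (a stratified sample across
  abundance quartiles, so rare and common taxa are represented) is split
  into two halves of *equal abundance mass* by greedy assignment in
  descending-abundance order; one half is multiplied by the fold change in
  group 1's ecosystem and the other half by the solved multiplier
  1 + (FC−1)·mass₁/mass₂ in group 2's, so both group vectors share one
  normalizer. Consequently non-true-positive taxa have *identical* relative
  abundance in both groups: differential abundance and differential
  relative abundance coincide exactly (asserted symbolically in the tests).
  A naive half-split without mass matching leaks the renormalization into
  every null taxon — exactly the artifact this design exists to remove.
  Mass-balanced partitioning was chosen over taxon duplication because
  duplication creates artificial twin taxa. The recorded truth carries the
  solved multipliers. Counts are drawn per family: multinomial on the group
  vector; Dirichlet-multinomial via Dirichlet(π·(1−θ)/θ) then multinomial
  (θ → 0 is the multinomial limit); gamma-Poisson with the gamma mean
  scaled by drawn depth over fitting depth (shape → ∞ is the Poisson /
  multinomial limit). The `original` design reproduces the older artifact:
  both groups sample one ecosystem and true positives are inflated *after*
  sampling, one-sidedly.
* **Compositional design:** ecosystem abundances of `tp_fraction` (default
  0.10) of taxa are multiplied by the fold change in group 1 only and both
  group vectors renormalized. The recorded truth is the ecosystem-level
  set; after renormalization *every* taxon differs in relative abundance
  (asserted in the tests), so FDR against this truth is precisely the
  penalty a relative-abundance test pays.
* **Null splits:** a one-group table is split randomly, or from the
  depth-sorted extremes with the deep window chosen to match a target mean
  library-size ratio (default 10×; closest attainable with a warning).
  Truth is empty, so every call is a false positive.

Template fitting uses closed-form moments throughout: row-sum proportions
(multinomial); mean sample proportions and a pooled variance-based θ with
the harmonic-mean depth correction, clipped to (1e-8, 1)
(Dirichlet-multinomial); per-taxon shape m²/(v−m) and rate m/(v−m) on
depth-standardized counts with a flagged Poisson limit when v ≤ m
(gamma-Poisson).

## Evaluation conventions

Sensitivity is |called ∩ truth|/|truth| (NA when truth is empty — that run
measures type-I error instead); FDR is |called \ truth|/|called| and is
defined as 0 when nothing is called, so that no-call replicates enter
averages instead of dropping out (an NA-propagating mode is a one-line
change away since the raw counts are returned too). Replicates aggregate by
median and type-7 75th percentile. The grid runner derives each cell's seed
deterministically from the base seed and the cell parameters, so reruns and
reordered grids reproduce identical records; failing cells are recorded and
skipped. The effect-size CDF uses Cohen's d on relative abundances — one
reasonable standardized effect among several, so it is labeled in the
output.

## Problem sizes and reproducibility

The shipped test-suite and acceptance runs use templates of 150–2000 taxa,
group sizes 5–100, depths around 1000–5000, and three replicates per cell —
sizes at which every stochastic check is stable under its fixed seeds while
the whole suite stays desk-scale. All randomness flows through explicit
seeds; every simulated dataset is exactly reproducible from its recorded
design and seed.

## Known limitations

* The synthetic templates have independent taxa; negative correlation
  enters only through the sampling constraint (multinomial/DM), and
  positive co-occurrence structure is absent.
* ANCOM's final cutoff is an approximation in both modes, and on very
  sparse tables the procedure is only meaningful after prevalence
  filtering (see above).
* The NB exact mode rounds size-factor-adjusted group sums to integers;
  with strongly varying size factors this is an approximation to a
  conditional test that does not exactly exist for non-integer data.
* The zero-inflated model is fit per the mixture described above, not as a
  re-implementation of any specific released package; likewise for all
  other compared methods — contracts, not code, are reproduced.
* PERMANOVA permutes raw sample labels (the classical scheme);
  residual-permutation schemes are not implemented.
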