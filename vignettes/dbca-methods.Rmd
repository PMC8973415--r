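---
title: "Dynamical brain complexity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical brain complexity analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbca)
```

## What the package computes

`dbca` quantifies the *dynamical complexity* of resting-state fMRI at two
levels.

**Voxel level.** A window of `Len` TRs slides along each voxel's BOLD series
in steps of one TR, and the sample entropy of each windowed segment is
computed, giving a 4D brain-entropy (BEN) map sequence per subject. The
per-voxel mean (Mean-BEN) and standard deviation (Std-BEN) over windows
summarise the level and the variability of transient complexity. Group
differences are assessed by a voxel-wise two-sample t-test with a
Monte-Carlo cluster-extent correction.

**Network level.** The BEN sequence is reduced to one entropy time series
per atlas region (mean over the region's defined voxels, per window).
Pearson correlations between regional entropy sequences give a subject's
connectivity matrix, which is binarised at proportional thresholds
`K = 0.05 … 0.30` (step 0.05) by keeping the strongest `K · R(R−1)/2`
edges. Each binary graph is characterised by the average clustering
coefficient `Cp`, characteristic path length `Lp`, their ratios to
degree-matched random networks (`γ = Cp/Crand`, `λ = Lp/Lrand`, small-world
index `S = γ/λ`), and global/local efficiency. Groups are compared by a
two-way group-by-threshold ANOVA per metric.

## Sample entropy

For a series of length `N`, embedding dimension `m` and tolerance `r`,
`SampEn = −ln(A/B)`, where `B` counts pairs of distinct length-`m`
templates whose Chebyshev distance is strictly below `r`, and `A` counts
the same pairs extended by one point. Conventions used here:

* the distance is the Chebyshev (max-coordinate) metric, the
  Richman–Moorman standard;
* self-matches are excluded, and only templates whose `(m+1)`-point
  extension exists are enumerated, so `A` and `B` range over the same pair
  set and normalisation constants cancel in the ratio;
* `r = r_factor · SD(segment)` with the sample SD (divisor `n − 1`),
  recomputed *per window per voxel*, which makes the estimate exactly
  invariant to shifting and positive rescaling of the signal. A global-`r`
  variant can be obtained by standardising the full series first; the
  per-window form is the default because each window is treated as its own
  stationary segment;
* degenerate cases return `NA` rather than a capped value: constant
  segments (`SD = 0`) and zero match counts (`A = 0` or `B = 0`). `NA`
  propagates into Mean-BEN/Std-BEN, and group statistics exclude voxels
  undefined in any subject.

Defaults `m = 2` and `r_factor = 0.3` follow standard practice for BOLD
complexity analyses.

### Window length and undefined values

With white-noise-like signals the expected number of `(m+1)`-template
matches grows roughly quadratically with window length. Below roughly 50–60
samples, `A = 0` occurs at a non-negligible rate, producing undefined
windows; at the default lengths (70–90 TRs) undefined voxels are rare. This
matters when choosing reduced problem sizes: the tests and the acceptance
script use windows of 60–70 TRs on series of 80–100 time points so that the
undefined-value pathway is exercised without dominating the maps.

The published window counts of 81/71/61 for `Len` = 70/80/90 are consistent
with the window-count identity `M = N − Len + 1` at an analysed series
length of 150 volumes (the common practice of discarding early volumes from
a 160-volume acquisition). `window_indices()` implements the identity for
any `N`; both facts are asserted in the tests.

## Graph metrics and the null model

* `Cp` is the mean Watts–Strogatz local clustering coefficient; nodes with
  degree < 2 contribute 0.
* `Lp` averages shortest-path lengths over *connected* node pairs only, and
  the number of unreachable pairs is reported alongside. At `K = 0.05`
  graphs of ~90 nodes are typically disconnected; excluding unreachable
  pairs keeps `Lp` finite without inventing a path length.
* Efficiency follows the Latora–Marchiori definitions: global efficiency is
  the mean inverse shortest-path length over ordered pairs (0 for
  unreachable pairs); local efficiency is the mean, over nodes, of the
  global efficiency of each node's neighbour subgraph, with degree-< 2
  nodes contributing 0.
* Edge ranking for proportional thresholding uses *signed* correlations by
  default (entropy sequences are expected to co-vary positively);
  absolute-value ranking is available via `rank = "absolute"`. Ties are
  broken lexicographically by (row, column), so thresholded graphs are
  bit-reproducible.
* The random reference is a Maslov–Sneppen degree-preserving rewiring
  ensemble: 100 null graphs by default, each from `10 · |E|` attempted
  double-edge swaps, fully seeded. `γ`, `λ` and `S` use the ensemble means
  `Crand` and `Lrand`.
* Metrics (including `S = γ/λ`) are computed per subject and then averaged
  across subjects. This matters: the mean of per-subject ratios is not the
  ratio of means, and published group tables are consistent with
  per-subject averaging.

## Group inference

The voxel-wise contrast is an independent two-sample t-test with pooled
variance, two-tailed. The cluster-extent correction re-implements the
AlphaSim logic: each Monte-Carlo iteration fills the analysis mask's grid
with i.i.d. Gaussian noise, smooths it with a separable Gaussian kernel of
the configured FWHM, re-standardises within the mask, applies the
two-tailed voxel threshold (`p = 0.01` by default), and records the largest
suprathreshold cluster under the chosen connectivity (26 by default). The
returned extent is the smallest `k` whose exceedance rate is at most
`alpha`. The forming threshold is two-tailed because both positive and
negative contrasts are of interest. For unsmoothed synthetic data the
appropriate smoothness is `fwhm_mm = 0`; for data smoothed at acquisition
resolution the published setting was 8 mm. Published cluster extents
(~200–210 voxels) depend on the original analysis mask and are treated as
plausibility references only.

The network-level comparison is an ordinary fixed-effects two-way ANOVA
with factors group and threshold, fitted per metric on the
subject-by-threshold table; the group main effect is the primary test, as
in the published tables. **Caveat:** a subject contributes one observation
per threshold and these derive from a single connectivity matrix, so they
are strongly correlated; the ordinary ANOVA treats them as independent and
is therefore anti-conservative for the group effect. The function emits a
note to this effect, and the type-I simulations in the test suite measure
the inflation directly (empirically the group-effect false-positive rate on
null cohorts is several times the nominal 5%). Repeated-measures and mixed
models are deliberately out of scope; a conservative alternative is to test
each threshold separately or to aggregate each subject's metric across
thresholds before a two-sample test. The seven metrics are not corrected
for multiple testing, matching the published presentation.

## Synthetic cohorts and what they do (and do not) show

The generator builds fully seeded two-group cohorts on a toy rectangular
grid atlas. Each voxel's series mixes a unit-SD deterministic component
(two low-frequency sinusoids, 0.02 and 0.05 Hz, region-specific phases)
with white Gaussian noise: `(1 − w)·det + w·noise + noise_sd·extra`. The
stochastic mix weight `w` is the complexity dial: expected sample entropy
rises monotonically with `w` through the operating range and saturates as
`w → 1` (a property of SampEn's noise response, verified by simulation in
the tests). `w` was chosen over AR(1) autocorrelation because its effect on
SampEn is monotone and easy to reason about; an AR(1)-style alternative can
be emulated by low-pass-filtering the noise upstream.

Defaults mirror the study design: 20 + 20 subjects, 160 time points at
TR = 2 s, baseline `w = 0.4`, planted effect regions at `w = 0.9` in group
A, voxel noise SD 0.1. The default 12×12×12 grid (27 regions) keeps a full
cohort run within minutes on one CPU; the acceptance runs use a 10×10×10
grid with 100 time points and 60-TR windows for the same reason, and those
sizes are stated where used.

For network-level effects, thresholded graph topology depends on the
*structure* of the correlation matrix, not its overall level — proportional
thresholding fixes the edge count. A uniform shared-noise component
therefore does not change topology. The generator instead plants topology
via slow noise-amplitude envelopes (sums of very-low-frequency sinusoids,
`exp(0.8·c·s(t))`): voxels sharing an envelope have co-fluctuating
windowed entropy, so entropy-sequence correlations follow the envelope's
sharing pattern. With `coupling_scope = "modular"` each module of regions
gets an independent envelope, yielding clustered, segregated networks;
`"global"` yields homogeneous ones. Contrasting the two scopes between
groups plants a detectable global-topology difference (higher `Cp`, lower
global efficiency in the modular group).

What passing these simulations does *not* show: the generator has no
hemodynamic response, physiological noise, motion artifacts, spatial
autocorrelation beyond region structure, or template-space geometry.
Results on real BOLD additionally depend on preprocessing (the pipeline
consumes preprocessed images and deliberately implements none of it).

## Numerical choices

* Strict inequality (`distance < r`) in template matching, as printed in
  the defining equations.
* Window iteration and voxel iteration are pure; results are independent of
  evaluation order.
* Proportional-threshold edge count is `round(K · R(R−1)/2)`.
* Cluster peaks are the voxel of maximal |t|; world coordinates are
  `affine · (i−1, j−1, k−1, 1)` (RAS+ mm, 0-based voxel convention).
* Seeds: every stochastic step (null ensembles, AlphaSim, cohort
  generation) takes an explicit seed and restores the caller's RNG state.

## Known limitations

* Entropy maps are not normalised (e.g. by global mean) before the t-test;
  whether the original analysis did so is unknown.
* One network per subject is built from the full entropy sequence;
  per-window dynamic networks are out of scope.
* Only binary graphs and scale-1 sample entropy are implemented;
  multi-scale entropy and weighted-graph metrics are out of scope.
* The ordinary two-way ANOVA's anti-conservatism discussed above.
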