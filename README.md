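# dbca — dynamical brain complexity analysis for resting-state fMRI

`dbca` measures how the *complexity* of brain activity differs between two
cohorts, at two levels:

1. **Dynamic brain-entropy mapping.** A window of `Len` TRs slides along
   each voxel's BOLD series (step 1 TR, so `N` time points give
   `M = N − Len + 1` windows). The sample entropy
   `SampEn(m, r) = −ln(A/B)` of each windowed segment — `B` the number of
   length-`m` template pairs within Chebyshev tolerance `r = 0.3·SD`, `A`
   the same pairs extended to length `m + 1` — gives a 4D brain-entropy
   (BEN) map sequence; its per-voxel mean (Mean-BEN) and SD (Std-BEN) are
   contrasted between groups with a voxel-wise two-sample t-test and an
   AlphaSim-style Monte-Carlo cluster-extent correction.
2. **Entropy-sequence networks.** Regional mean entropy sequences are
   correlated (Pearson) to form a connectivity matrix per subject,
   binarised at proportional thresholds `K = 0.05 … 0.30`. Each graph is
   summarised by clustering coefficient `Cp`, path length `Lp`, their
   random-network-normalised ratios `γ = Cp/Crand`, `λ = Lp/Lrand`,
   small-world index `S = γ/λ`, and global/local efficiency
   (`E_glob = mean 1/d_ij`, `E_loc` over neighbour subgraphs). Metrics are
   compared by a two-way group × threshold ANOVA.

It is written for neuroimaging researchers who have *preprocessed* 4D NIfTI
data (or want fully synthetic ground-truth cohorts) and want a tested,
scriptable implementation of the whole chain: entropy mapping → summary
maps → corrected contrasts, and entropy networks → topology → ANOVA.

A fully seeded synthetic-cohort generator (`synthetic_spec()`,
`generate_cohort()`) emulates the two-group study design with regionally
controlled signal regularity, so every stage can be validated against known
ground truth.

## Worked example

```r
library(dbca)

# a 10x10x10 two-group cohort, 20 + 20 subjects, 100 time points,
# one planted high-complexity region (region 14) in group A
spec <- synthetic_spec(grid_shape = c(10, 10, 10), n_regions = 27,
                       n_timepoints = 100, n_per_group = 20,
                       effect_regions = 14L, seed = 11)
cohort <- generate_cohort(spec)

arm <- run_entropy_arm(cohort, window_lengths = 60,
                       alphasim = alphasim_config(fwhm_mm = 0,
                                                  n_iterations = 200,
                                                  seed = 5))
arm$len60$clusters
#> # A tibble: 1 × 10
#>   direction  size peak_stat peak_x peak_y peak_z peak_i peak_j peak_k label
#>   <chr>     <int>     <dbl>  <dbl>  <dbl>  <dbl>  <int>  <int>  <int> <chr>
#> 1 positive     11      5.84     15     18     12      6      7      5 region_14
```

One corrected cluster survives: 11 voxels, peak t = 5.84 at voxel
(6, 7, 5) — inside the planted region 14 — i.e. group A's Mean-BEN is
credibly higher exactly where the generator made its signal less regular.
The extent threshold (`arm$len60$extent`, here 4 voxels) came from the
seeded Monte-Carlo simulation on the same mask.

The network arm, on a cohort with modular vs global complexity
co-fluctuation:

```r
spec2 <- synthetic_spec(grid_shape = c(10, 10, 10), n_regions = 27,
                        n_timepoints = 100, n_per_group = 10,
                        coupling = c(A = 0.8, B = 0.8),
                        coupling_scope = c(A = "modular", B = "global"),
                        seed = 21)
net <- run_network_arm(generate_cohort(spec2), window_length = 60,
                       null_cfg = null_model_config(n_random = 0, seed = 2))
tidy(net$anova)
#> # A tibble: 4 × 5
#>   metric f_group  p_group p_threshold p_interaction
#> 1 cp       28.4  5.51e- 7    5.58e-37        0.966
#> 2 lp       18.5  3.70e- 5    3.05e- 1        0.605
#> 3 e_glob   67.9  4.45e-13    2.42e-46        0.0437
#> 4 e_loc    14.6  2.19e- 4    2.33e-41        0.958
```

The modular group shows higher clustering and markedly lower global
efficiency at every threshold (`cell_mean_table(net$anova)` prints the
2 × 6 group-by-threshold cell means); the group main effect is the primary
p-value, as in standard reports of this analysis. `autoplot(net$metrics)`
draws the metric-vs-K curves per group.

A thin command-line wrapper is provided at `inst/cli/dbca.R`
(`simulate`, `entropy`, `contrast`, `network`, `run` subcommands over
NIfTI/TSV/JSON artifacts).

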