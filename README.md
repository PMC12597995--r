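# imtx — imaging transcriptomics for two-group brain studies

`imtx` is an R package for researchers who have voxelwise brain maps from
two groups — resting-state ALFF (amplitude of low-frequency fluctuations)
and/or arterial-spin-labeling cerebral blood flow (CBF) — and want to ask
two questions in one reproducible pipeline:

1. **Where do the groups differ?** Covariate-adjusted voxelwise group
   contrasts with Gaussian-random-field (GRF) cluster-level correction
   (voxel P < 0.001, cluster P < 0.05), plus the usual demographic
   two-sample t and chi-squared tests.
2. **Which genes' regional expression tracks those differences?** A
   donor-averaged regions x genes expression matrix (sample-to-region
   assignment, inter-donor stability filtering at mean pairwise r > 0.1,
   robust-sigmoid normalization), related to the regional t map by
   first-component partial least squares (PLS1), with region-permutation
   significance for the spatial correlation, bootstrap z-scores per gene,
   intersection of the per-modality gene sets, and hypergeometric
   over-representation analysis against GMT annotations.

## The statistics at the core

For expression matrix `X` (regions x genes, columns z-scored) and a
regional effect map `y` (centred):

- PLS1 weights `w = Xᵀy / ‖Xᵀy‖`, scores `s = Xw`, spatial correlation
  `r = cor(s, y)` (sign fixed so `r ≥ 0`); `w` equals the first singular
  vector of the cross-covariance `Xᵀy`.
- Permutation p: `(1 + #{r_perm ≥ r_obs}) / (1 + n_perm)` over
  region-shuffled `y` (floor 1e-4 at the default 10,000 permutations).
- Bootstrap gene z: regions resampled with replacement, replicate weights
  sign-aligned to the original, `z_g = w_g / SD_boot(w_g)`, two-sided
  normal p, Benjamini–Hochberg q; genes selected at `p < 0.05`.
- GRF cluster p: `1 − exp(−E[m] · exp(−β k^{2/3}))` with `E[m]` the
  expected two-sided cluster count from the Euler-characteristic density
  at the z-equivalent threshold and the RESEL count
  `V / ∏ FWHM_axis` estimated from normalized-residual derivatives.
- Enrichment: fold `(k/n)/(K/N)` and the hypergeometric tail
  `P(X ≥ k)`, BH-FDR within annotation category.

A fully seeded synthetic-cohort generator (imaging volumes, donor
expression tables with planted loading genes, GMT annotations with
planted enriched terms) gives every stage a parameter-recovery test.

## Worked example

```r
library(imtx)

# Table-style demographics from printed summaries (control group first)
demographic_t(2.00, 2.10, 32, 23.44, 7.60, 34, "welch")
#> # A tibble: 1 × 4
#>       t    df        p variant
#>   <dbl> <dbl>    <dbl> <chr>
#> 1 -15.8  38.3 2.19e-18 welch

# A complete synthetic study written to disk and analysed end to end
demo <- run_demo("demo_out", seed = 1)

demo$manifest$pls_results$alff
#> <pls_result> 36 regions x 199 genes; spatial r = 0.837, permutation p = 0.001; bootstrap over 500 draws

demo$region_recovery[, 1:4]
#> # A tibble: 2 × 4
#>   modality n_planted n_recovered recovery
#>   <chr>        <int>       <int>    <dbl>
#> 1 alff             3           3        1
#> 2 cbf              3           3        1

glance(demo$manifest$pls_results$cbf)
#> # A tibble: 1 × 5
#>   n_regions n_genes     r perm_p n_selected
#>       <int>   <int> <dbl>  <dbl>      <int>
#> 1        36     199 0.848  0.001         75

head(demo$manifest$enrichment$alff[, c("term_id", "k", "fold_enrichment", "p", "q")], 3)
#> # A tibble: 3 × 5
#>   term_id     k fold_enrichment       p      q
#>   <chr>   <int>           <dbl>   <dbl>  <dbl>
#> 1 T0001       8            2.56 0.00102 0.0102
#> 2 T0009       9            1.37 0.166   0.647
#> 3 T0013       7            1.35 0.229   0.647
```

Reading the output: both synthetic arms (a 4D BOLD cohort carrying a
band-limited amplitude effect and a 3D perfusion cohort carrying a
regional shift, 16 subjects per arm here) recover all three planted
regions as GRF-surviving clusters; the regional t maps correlate with the
PLS1 expression scores at r ≈ 0.84 with the permutation p at its floor
(999 permutations); and the first annotation term — planted to draw its
members from the loading genes — tops the enrichment table at q ≈ 0.01.
`T0001` is a planted term (`demo$truth$planted_terms`).

The same `run_pipeline(config)` call runs on real data: NIfTI volumes
listed in a per-modality manifest TSV (`subject_id, group, age, sex,
mean_fd, path`), an integer-label atlas with a region table, donor
expression TSVs (`donor_id, x_mm, y_mm, z_mm, <gene columns>`), and GMT
files, all referenced from one YAML config with a mandatory seed.

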