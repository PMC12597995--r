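---
title: "Linking regional brain-imaging contrasts to gene expression with imtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking regional brain-imaging contrasts to gene expression with imtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imtx)
```

## The analysis imtx implements

imtx ties together two strands of evidence about a two-group neuroimaging
study — typically patients versus matched controls:

1. **Where the groups differ.** Voxelwise maps of resting-state activity
   (ALFF, the amplitude of low-frequency fluctuations of the BOLD signal)
   and of perfusion (arterial-spin-labeling cerebral blood flow, z-scored
   within the brain) are contrasted between groups with a
   covariate-adjusted linear model and corrected for multiple comparisons
   with Gaussian-random-field (GRF) cluster inference.
2. **Which genes track those differences in space.** The unthresholded t
   map is averaged within the regions of a parcellation atlas and related
   to a donor-averaged regions-by-genes expression matrix with a
   first-component partial-least-squares analysis (PLS1). Significance of
   the spatial correlation comes from region permutation; per-gene
   reliability from a region bootstrap. The gene sets selected for the two
   modalities are intersected and carried into hypergeometric
   over-representation analysis against user-supplied GMT annotation
   files.

Every stage also exists in a synthetic flavour: the package ships a
cohort/expression/annotation generator with known ground truth, so the
whole pipeline is exercised and validated by parameter recovery without
any external download.

## Stage by stage

### ALFF

For each voxel the series is linearly detrended and Fourier transformed;
the single-sided amplitude spectrum is `a_f = 2 |X_f| / T`, and ALFF is
the mean of `a_f` over the DFT bins whose frequencies fall in the closed
band `[0.01, 0.10]` Hz. Two conventions are pinned down here because
"square root of the power spectrum" alone does not fix a scale: the `2/T`
single-sided normalization, and closed-interval bin inclusion. Group
contrasts are invariant to both. With these conventions a pure sinusoid
of amplitude `A` at an exact in-band bin yields `ALFF = A/K` for `K` band
bins — but only with detrending disabled, since the detrend projection
leaks a term of order `A/k^2` into bin `k`; the analytic tests therefore
call `compute_alff(..., detrend = FALSE)`. No division by the global mean
is applied (a `standardize = "mean"` flag provides mALFF if wanted); the
group model's intercept absorbs scale.

### CBF normalization and smoothing

`zscore_volume()` centres and scales each perfusion map within a
whole-brain mask, using the population-SD convention (divide by N) so
that a three-voxel example `(1, 2, 3)` maps exactly to
`(-1.2247, 0, 1.2247)`. `gaussian_smooth()` performs separable Gaussian
convolution with `sigma = fwhm / (voxel * 2 sqrt(2 ln 2))` per axis,
zero-padded at the grid edge, mask applied after smoothing; the default
kernel is the study's 8 mm FWHM (the synthetic demo uses 6 mm on its
3 mm grids). Zero padding keeps the Gaussian semigroup property testable
in the grid interior and preserves the total image mass for
interior-supported images. Input resampling to a common grid is treated
as upstream preprocessing; the pipeline starts from aligned volumes.

### Group inference

`fit_group_glm()` fits `value ~ group + sex + age + mean FD` per voxel by
OLS and returns the group t map, the contrast-estimate map and the
residuals. With no covariates the t map reproduces the pooled two-sample
t exactly. Note one subtlety we pin down in tests: adding a covariate
orthogonal to the group column leaves the contrast *estimate* unchanged
(an exact OLS property), while the t value still moves slightly because
the error variance is re-estimated on one fewer degree of freedom.

Smoothness for GRF correction is estimated from the variance of spatial
derivatives of unit-normalized residuals: per axis
`FWHM = sqrt(4 ln 2 / lambda)` with `lambda` the mean squared neighbour
difference, and `RESELs = in-mask voxels / prod(FWHM_vox)`. This simple
estimator has a known mild upward bias at low smoothness (about 9% at a
2-voxel FWHM, about 2% at 4 voxels, from the discrete-lag approximation
of the derivative variance); the simulation test requires recovery
within 15% of the generating kernel and the calibration test below
absorbs the residual bias.

Cluster correction thresholds `|t|` at the two-sided 0.001 quantile for
the fit's df, forms 26-connected clusters per sign, and computes each
cluster's corrected p from the expected-cluster-count and extent
approximations for Gaussian fields, using the probability-matched
z-equivalent threshold. The expected cluster count is taken for the
two-sided excursion set (twice the one-tail Euler-characteristic
density), so the family-wise rate over the whole map — not per tail — is
controlled at the nominal 0.05. On 500 simulated smooth null fields the
observed family-wise cluster false-positive rate is below the nominal
level (the approximation errs conservative at these smoothness levels),
which the acceptance suite verifies against a 0.07 ceiling.

### The expression matrix

Donor samples arrive as MNI coordinates plus a gene vector.
`assign_samples()` maps each sample to the region of the nearest labelled
voxel within 2 mm (a common toolbox default); unmatched samples are
dropped, and unsampled regions stay *absent* rows rather than zeros.
`filter_stable_genes()` keeps genes whose regional profiles correlate
across donor pairs (mean pairwise Pearson r strictly above 0.1, computed
over each pair's shared regions; pairs with fewer than 3 shared regions
are skipped). `combine_donors()` normalizes each gene within each donor —
scaled robust sigmoid by default (sigmoid at the median scaled by
IQR/1.349, min-max rescaled to [0, 1]), with `zscore` and `none` as
alternatives — then averages donors element-wise, ignoring missing rows.
The normalization choice is exposed because the source material does not
fix it; robust sigmoid is the default of the standard aggregation
toolbox in this field.

### PLS1, permutation and bootstrap

With the expression matrix `X` (columns z-scored across regions) and the
regional t map `y` (centred), the first PLS component has weights
`w = X'y / ||X'y||`, scores `s = Xw`, and spatial correlation
`r = cor(s, y)`, with the sign fixed so `r >= 0`. This equals the first
singular vector of the cross-covariance `X'y`, which the tests verify
against an SVD oracle at 1e-10.

The permutation test refits on region-shuffled `y` (`p` with the add-one
convention, so `n_perm = 9999` gives the 1e-4 floor). Because `X` is
unchanged by permuting `y`, the implementation standardizes `X` once and
evaluates all refits as blocked matrix products — bit-equivalent to the
literal refit, which a test asserts. The null model permutes region
labels freely; spatial-autocorrelation-preserving nulls (spin or
variogram-matched permutations) are a documented extension point, and
results on strongly autocorrelated maps will be anti-conservative
relative to them.

The bootstrap resamples regions with replacement, refits, aligns each
replicate's weight sign with the original (by the sign of the dot
product), and reports `z = w / SD_boot(w)` per gene with two-sided
normal p and BH q. Gene sets are selected at bootstrap `p < 0.05` by
default; q values are reported alongside.

**A calibration caveat worth knowing.** Under a global null (no
association anywhere) the sign-alignment step biases the bootstrap SD
downward — the replicate direction is arbitrary, and aligning it to the
observed weights clips half of the sampling distribution — so selection
at `p < 0.05` admits roughly 18–21% of null genes across 36–300 regions
in our simulations. When a real component pins the direction and the
tested universe is dominated by signal-tracking genes (as after a
stringent stability filter), observed FDR is low and the recovery tests
pass comfortably; but when the universe contains many donor-stable,
phenotype-unrelated genes, p-based selection is liberal and the q column
is the safer guide. This behaviour is a property of the procedure, not of
the implementation; we report it rather than alter the method.

### Enrichment

`enrich()` computes, per term, the overlap `k`, fold enrichment
`(k/n)/(K/N)`, the one-sided hypergeometric tail `P(X >= k)` (an EASE
variant testing at `k - 1` is available behind a flag), and BH q within
each annotation category (BP/CC/MF/PATHWAY) by default, with a
global-FDR option. The universe is the post-stability-filter gene list —
the population actually tested — rather than all annotated genes. Terms
are intersected with the universe first, and overlaps below
`min_overlap = 2` are dropped before FDR.

## The synthetic generator: what it emulates, and what it does not

`generate_bold_cohort()` injects, in patients only, a sinusoid at the
band-interior DFT frequency nearest the band centre into the voxels of
chosen atlas regions, on top of white Gaussian noise; the injected ALFF
difference has the closed form `effect_size * noise_sd / K`.
`generate_cbf_cohort()` adds a regional mean shift, a voxel-level
Cohen's d equal to `effect_size`. Covariates mirror the cohort the
pipeline was built around: age ~ Normal(23, 6.5) truncated to [14, 59]
(truncation lifts the realized mean to about 23.6), sex ~ Bernoulli with
the female-majority rate 52/66, and mean framewise displacement drawn
per group from Normal(0.62, 0.31) and Normal(0.51, 0.16), truncated
positive. Unequal default arms (34/32) match that regime. Effects sit on
atlas-region support so region-level recovery is exactly scorable.

`generate_donor_expression()` gives each loading gene the profile
`loading * latent_map + donor noise`, with loading magnitudes near 1
(signs random) so planted genes are recoverable rather than vanishing at
zero; non-loading genes are pure donor noise by default, which makes the
stability filter's null behaviour testable against the correlation null.
A positive `background_sd` instead gives non-loading genes donor-shared
spatial profiles mixing a handful of common components
(`background_factors = 5`), emulating two facts about real expression
atlases: most genes pass a donor-stability filter, and regional
expression is dominated by a few spatial components. The demo uses this
mode so the tested universe stays much larger than the selected sets.
Each donor omits a random `missing_rate` of regions as absent rows.

Deliberately *not* emulated: physiological and motion-structured fMRI
noise, scanner drift, spatially varying smoothness, hemispheric
symmetry, probe-level microarray preprocessing, and spatial
autocorrelation in the imaging noise beyond what smoothing induces.
Passing recovery tests therefore demonstrates that the statistical
machinery is correct and calibrated under its stated model — not that
effect sizes of this magnitude are detectable in real cohorts with
structured noise.

## Numerical and design choices

* Problem sizes in tests and the acceptance script are desk-scale by
  design: grids of 16–24 voxels per axis, 24–100 regions, 120–500 genes,
  199–999 permutations and 200–1000 bootstrap draws; recovery claims
  average 10–20 seeds. These sizes were chosen so the full validation
  remains quick while every statistical property under test (calibration
  rates, recovery bounds, oracle equalities) is already stable.
* All generators and resampling routines take explicit integer seeds and
  restore the caller's RNG state; the pipeline config requires a seed and
  derives per-stage seeds from it, making reruns bit-identical.
* Degenerate inputs fail loudly: constant images cannot be z-scored,
  bands containing no DFT bin report the minimum series length, designs
  must be full rank with two subjects per arm, a constant bootstrap
  resample is redrawn (capped), and empty retained-gene sets are errors.
* Ties: the stability filter honours the strict inequality `> 0.1`; the
  permutation count uses `>=` on `r` with a 1e-12 guard; BH is the
  standard step-up.
* The `auto` variant of the raw-data two-sample t test gates on Levene's
  test at alpha 0.05 (absolute deviations from group means), matching the
  reporting convention of mainstream statistics packages; from printed
  summaries the caller chooses pooled or Welch explicitly.

## Limitations

* GRF cluster inference relies on Gaussian-field approximations; at
  smoothness below ~2 voxels FWHM or very low df it turns conservative
  (our calibration shows rates well under nominal rather than above).
* The permutation null ignores spatial autocorrelation of the regional
  map; see the extension point above.
* Bootstrap-z gene selection at `p < 0.05` is liberal under weak signal
  (see the caveat in the PLS section).
* The z-scored perfusion maps are *relative*: a focal true increase
  induces genuine low-amplitude opposite-signed shifts elsewhere in the
  map, which large-n contrasts can detect. This is a property of
  relative normalization, visible in the synthetic recovery runs as
  extra negative clusters, and worth remembering when interpreting real
  zCBF contrasts.

## A minimal run

```{r, eval = FALSE}
demo <- run_demo("demo_out", seed = 1)
demo$region_recovery
demo$gene_recovery
glance(demo$manifest$pls_results$alff)
autoplot(demo$manifest$pls_results$alff)
plot_enrichment(demo$manifest$enrichment$alff)
```

`run_demo()` writes a complete study (NIfTI volumes, covariate and donor
TSVs, GMT files, a YAML config), runs `run_pipeline()` on those files,
and scores recovery against the generator truth. `run_pipeline()` works
identically on real data given the same file layout.
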