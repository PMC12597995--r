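test_that("cohort generators are byte-identical under a fixed seed", {
  atlas <- synthetic_atlas(c(8, 8, 6), 10, 3)
  spec <- cohort_spec(n_per_group = 3, grid_shape = c(8, 8, 6),
                      n_timepoints = 64, effect_regions = 2L, seed = 42)
  a <- generate_bold_cohort(spec, atlas)
  b <- generate_bold_cohort(spec, atlas)
  expect_identical(lapply(a$volumes, vol_data), lapply(b$volumes, vol_data))
  expect_identical(a$covariates, b$covariates)
  c1 <- generate_cbf_cohort(spec, atlas)
  c2 <- generate_cbf_cohort(spec, atlas)
  expect_identical(lapply(c1$volumes, vol_data), lapply(c2$volumes, vol_data))
})

test_that("an out-of-band oscillation request is an invalid spec", {
  expect_error(cohort_spec(tr = 1, band = c(0.01, 0.6)), "Nyquist")
  expect_error(cohort_spec(band = c(0.1, 0.01)), "Nyquist")
  atlas <- synthetic_atlas(c(8, 8, 6), 10, 3)
  spec <- cohort_spec(n_per_group = 2, grid_shape = c(8, 8, 6),
                      effect_regions = 99L, seed = 1)
  expect_error(generate_bold_cohort(spec, atlas), "subset")
})

test_that("a noiseless injected sinusoid propagates exactly into ALFF", {
  atlas <- synthetic_atlas(c(6, 6, 4), 6, 3)
  # with noise_sd = 0 both groups carry only the baseline amplitude
  spec2 <- cohort_spec(n_per_group = 2, grid_shape = c(6, 6, 4),
                       n_timepoints = 200, effect_regions = 3L,
                       effect_size = 0, noise_sd = 0, baseline = 1.5,
                       seed = 5)
  coh2 <- generate_bold_cohort(spec2, atlas)
  alff <- compute_alff(coh2$volumes[[1]], coh2$mask, detrend = FALSE)
  lab <- vol_data(atlas$labels)
  k <- coh2$truth$n_band_bins
  expect_equal(unique(round(vol_data(alff)[lab == 3L], 10)),
               round(1.5 / k, 10))
  expect_true(all(vol_data(alff)[lab %in% c(1L, 2L)] == 0))
})

test_that("a null effect leaves no systematic group ALFF difference", {
  atlas <- synthetic_atlas(c(8, 8, 6), 8, 3)
  spec <- cohort_spec(n_per_group = 12, grid_shape = c(8, 8, 6),
                      n_timepoints = 80, effect_regions = 4L,
                      effect_size = 0, seed = 31)
  coh <- generate_bold_cohort(spec, atlas)
  alffs <- vapply(seq_along(coh$volumes), function(i) {
    a <- compute_alff(coh$volumes[[i]], coh$mask)
    mean(vol_data(a)[vol_data(atlas$labels) == 4L])
  }, numeric(1))
  grp <- coh$covariates$group == "MDD"
  expect_gt(stats::t.test(alffs[grp], alffs[!grp])$p.value, 0.01)
})

test_that("perfusion effects have the designed voxel-level power and null rate", {
  # d = 2, n = 50/arm: nearly every effect voxel crosses the P<0.001 threshold
  atlas <- synthetic_atlas(c(10, 10, 8), 10, 3)
  spec <- cohort_spec(n_per_group = 50, grid_shape = c(10, 10, 8),
                      effect_regions = c(2L, 6L), effect_size = 2, seed = 8)
  coh <- generate_cbf_cohort(spec, atlas)
  des <- data.frame(group = as.integer(coh$covariates$group == "MDD"))
  fit <- fit_group_glm(coh$volumes, des, coh$mask)
  thr <- qt(1 - 0.001 / 2, fit$df)
  eff <- vol_data(atlas$labels) %in% c(2L, 6L)
  expect_gt(mean(vol_data(fit$t)[eff] > thr), 0.9)

  # null cohort: false-positive rate about 0.001 over >= 1e5 voxels
  spec0 <- cohort_spec(n_per_group = 20, grid_shape = c(50, 50, 40),
                       effect_regions = integer(), effect_size = 0, seed = 9)
  atlas0 <- synthetic_atlas(c(50, 50, 40), 8, 3)
  coh0 <- generate_cbf_cohort(spec0, atlas0)
  fit0 <- fit_group_glm(coh0$volumes,
                        data.frame(group = as.integer(
                          coh0$covariates$group == "MDD")),
                        coh0$mask)
  rate <- mean(abs(vol_data(fit0$t)[coh0$mask$data > 0]) >
                 qt(1 - 0.001 / 2, fit0$df))
  expect_gt(rate, 0.0004)
  expect_lt(rate, 0.002)
})

test_that("cohort covariates follow the configured demographic regime", {
  atlas <- synthetic_atlas(c(6, 6, 4), 4, 3)
  spec <- cohort_spec(n_per_group = c(300, 300), grid_shape = c(6, 6, 4),
                      effect_regions = integer(), seed = 13)
  cov <- generate_cbf_cohort(spec, atlas)$covariates
  expect_true(all(cov$age >= 14 & cov$age <= 59))
  # truncation at 14 shifts the mean of N(23, 6.5) up to about 23.6
  expect_gt(mean(cov$age), 23)
  expect_lt(mean(cov$age), 24.6)
  expect_equal(mean(cov$sex == "F"), 52 / 66, tolerance = 0.1)
  expect_gt(mean(cov$mean_fd[cov$group == "MDD"]),
            mean(cov$mean_fd[cov$group == "HC"]))
  expect_true(all(cov$mean_fd > 0))
})

test_that("donor expression has the atlas-scale shape with missing rows", {
  es <- expression_spec(n_regions = 636, n_genes = 40, n_donors = 6,
                        missing_rate = 0.15, seed = 3)
  ge <- generate_donor_expression(es)
  expect_length(ge$donors, 6)
  miss_frac <- vapply(ge$donors, function(d) {
    expect_equal(dim(d$matrix$values), c(636L, 40L))
    mean(rowSums(!is.na(d$matrix$values)) == 0)
  }, numeric(1))
  expect_equal(mean(miss_frac), 0.15, tolerance = 0.035)
  # missing rows are wholly absent, never zeros
  for (d in ge$donors) {
    na_rows <- rowSums(is.na(d$matrix$values))
    expect_true(all(na_rows %in% c(0L, 40L)))
  }
})

test_that("noise-free loading genes correlate perfectly with the latent map", {
  es <- expression_spec(n_regions = 30, n_genes = 20, n_donors = 3,
                        loading_fraction = 0.5, noise_sd = 0,
                        missing_rate = 0, seed = 6)
  ge <- generate_donor_expression(es)
  vals <- ge$donors[[1]]$matrix$values
  for (g in ge$truth$loading_genes) {
    expect_equal(abs(cor(vals[, g], ge$truth$latent_map$value)), 1,
                 tolerance = 1e-12)
  }
  non <- setdiff(ge$truth$gene_ids, ge$truth$loading_genes)
  expect_true(all(vals[, non] == 0))  # pure noise with sd 0
})

test_that("same expression seed reproduces matrices and sample tables", {
  atlas <- synthetic_atlas(c(8, 8, 6), 12, 3)
  es <- expression_spec(n_regions = 12, n_genes = 15, n_donors = 2, seed = 11)
  a <- generate_donor_expression(es, atlas)
  b <- generate_donor_expression(es, atlas)
  expect_identical(a$donors[[1]]$matrix$values, b$donors[[1]]$matrix$values)
  expect_identical(a$donors[[2]]$samples$coords, b$donors[[2]]$samples$coords)
  expect_identical(a$truth$loadings, b$truth$loadings)
})

test_that("annotation generation plants enriched terms and round-trips GMT", {
  es <- expression_spec(n_regions = 20, n_genes = 120,
                        loading_fraction = 0.25, seed = 2)
  ge <- generate_donor_expression(es)
  ann <- generate_annotation(ge$truth$gene_ids, ge$truth, n_terms = 12,
                             term_size_range = c(10, 20), n_planted = 2,
                             seed = 9)
  expect_length(ann$planted_terms, 2)
  for (tid in ann$planted_terms) {
    members <- ann$collection$genes[[match(tid, ann$collection$term_id)]]
    frac <- mean(members %in% ge$truth$loading_genes)
    expect_gte(frac, 0.7)
  }
  # same seed -> identical GMT bytes
  p1 <- withr::local_tempfile(fileext = ".gmt")
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann$collection, p1)
  ann2 <- generate_annotation(ge$truth$gene_ids, ge$truth, n_terms = 12,
                              term_size_range = c(10, 20), n_planted = 2,
                              seed = 9)
  write_gmt(ann2$collection, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(generate_annotation(letters[1:5], NULL, n_terms = 3,
                                   term_size_range = c(2, 10)),
               "exceeds")
})
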