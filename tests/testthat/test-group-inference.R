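test_that("the GLM group t equals the pooled two-sample t with no covariates", {
  set.seed(10)
  shape <- c(6, 6, 4)
  n <- 8
  maps <- lapply(1:(2 * n), function(i)
    brain_vol(array(rnorm(prod(shape)), shape)))
  fit <- fit_group_glm(maps, data.frame(group = rep(c(1, 0), each = n)),
                       full_mask(shape))
  expect_equal(fit$df, 2 * n - 2)
  for (v in c(1, 37, 100)) {
    g1 <- vapply(maps[1:n], function(m) vol_data(m)[v], numeric(1))
    g2 <- vapply(maps[(n + 1):(2 * n)], function(m) vol_data(m)[v], numeric(1))
    tt <- unname(stats::t.test(g1, g2, var.equal = TRUE)$statistic)
    expect_equal(vol_data(fit$t)[v], tt, tolerance = 1e-10)
  }
})

test_that("a covariate orthogonal to group leaves the contrast unchanged", {
  set.seed(11)
  shape <- c(5, 5, 3)
  n <- 12
  maps <- lapply(1:n, function(i) brain_vol(array(rnorm(prod(shape)), shape)))
  g <- rep(c(0, 1), each = n / 2)
  z <- stats::residuals(stats::lm(rnorm(n) ~ g))  # orthogonal to [1, group]
  fit0 <- fit_group_glm(maps, data.frame(group = g), full_mask(shape))
  fit1 <- fit_group_glm(maps, data.frame(group = g, z = z), full_mask(shape),
                        covariates = "z")
  # OLS orthogonality: the group contrast estimate is unchanged; the t
  # map changes only through the error-variance re-estimate
  expect_equal(vol_data(fit1$beta), vol_data(fit0$beta), tolerance = 1e-8)
  expect_equal(fit1$df, fit0$df - 1)
  expect_equal(sign(vol_data(fit1$t)), sign(vol_data(fit0$t)))
})

test_that("voxelwise null calibration holds at the P < 0.001 threshold", {
  set.seed(12)
  shape <- c(50, 50, 40)  # 1e5 voxels
  n <- 10
  maps <- lapply(1:(2 * n), function(i)
    brain_vol(array(rnorm(prod(shape)), shape)))
  fit <- fit_group_glm(maps, data.frame(group = rep(0:1, n)),
                       full_mask(shape))
  thr <- qt(1 - 0.001 / 2, df = fit$df)
  rate <- mean(abs(vol_data(fit$t)) > thr)
  expect_gt(rate, 0.0005)
  expect_lt(rate, 0.002)
})

test_that("rank-deficient designs and tiny groups are rejected", {
  shape <- c(4, 4, 3)
  maps <- lapply(1:6, function(i) brain_vol(array(rnorm(48), shape)))
  expect_error(fit_group_glm(maps, data.frame(group = c(1, 1, 1, 1, 1, 0)),
                             full_mask(shape)), "2 subjects")
  d <- data.frame(group = rep(0:1, each = 3), dup = rep(0:1, each = 3))
  expect_error(fit_group_glm(maps, d, full_mask(shape), covariates = "dup"),
               "rank deficient")
})

test_that("smoothness estimates recover the generating kernel", {
  set.seed(13)
  shape <- c(40, 40, 40)
  vs <- 3
  fwhm <- 6
  maps <- lapply(1:12, function(i)
    gaussian_smooth(brain_vol(array(rnorm(prod(shape)), shape),
                              voxel_size = vs), fwhm))
  fit <- estimate_smoothness(
    fit_group_glm(maps, data.frame(group = rep(0:1, 6)), full_mask(shape)))
  expect_true(all(abs(fit$smoothness$fwhm_mm - fwhm) / fwhm < 0.15))

  # unsmoothed white noise: FWHM close to one voxel
  maps0 <- lapply(1:12, function(i)
    brain_vol(array(rnorm(prod(shape)), shape), voxel_size = vs))
  fit0 <- estimate_smoothness(
    fit_group_glm(maps0, data.frame(group = rep(0:1, 6)), full_mask(shape)))
  expect_true(all(abs(fit0$smoothness$fwhm_vox - 1) < 0.25))
})

test_that("RESELs scale linearly with mask volume at fixed smoothness", {
  set.seed(14)
  shape <- c(30, 30, 20)
  maps <- lapply(1:10, function(i)
    gaussian_smooth(brain_vol(array(rnorm(prod(shape)), shape)), 3))
  design <- data.frame(group = rep(0:1, 5))
  full <- estimate_smoothness(fit_group_glm(maps, design, full_mask(shape)))
  half_mask <- array(FALSE, shape)
  half_mask[, , 1:10] <- TRUE
  half <- estimate_smoothness(fit_group_glm(maps, design, half_mask))
  ratio <- full$smoothness$resels / half$smoothness$resels
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("GRF cluster p is monotone in cluster size and respects threshold", {
  # direct check on the extent distribution at fixed smoothness
  e_m <- 2 * imtx:::grf_expected_clusters(qnorm(1 - 0.0005), 500)
  e_n <- 1e5 * 2 * pnorm(-qnorm(1 - 0.0005))
  beta <- (gamma(2.5) * e_m / e_n)^(2 / 3)
  p_of_k <- function(k) 1 - exp(-e_m * exp(-beta * k^(2 / 3)))
  ks <- c(1, 5, 10, 50, 200)
  expect_true(all(diff(p_of_k(ks)) <= 0))
})

test_that("a planted regional effect yields a surviving cluster at its site", {
  atlas <- synthetic_atlas(c(16, 16, 12), 20, 3)
  spec <- cohort_spec(n_per_group = 30, grid_shape = c(16, 16, 12),
                      effect_regions = 7L, effect_size = 2, seed = 21)
  coh <- generate_cbf_cohort(spec, atlas)
  sm <- lapply(coh$volumes, function(v)
    gaussian_smooth(zscore_volume(v, coh$mask), 6, mask = coh$mask))
  des <- data.frame(group = as.integer(coh$covariates$group == "MDD"),
                    age = coh$covariates$age, sex = coh$covariates$sex,
                    mean_fd = coh$covariates$mean_fd)
  fit <- fit_group_glm(sm, des, coh$mask,
                       covariates = c("age", "sex", "mean_fd"))
  cl <- grf_cluster_correct(fit)
  expect_gt(nrow(cl), 0)
  rec <- score_region_recovery(cl, atlas, 7L)
  expect_equal(rec$recovery, 1)
  pos <- dplyr::filter(cl, sign == "positive")
  expect_gt(max(pos$peak_t), qt(1 - 0.0005, fit$df))
})

test_that("no suprathreshold voxels gives an empty cluster table", {
  set.seed(15)
  shape <- c(8, 8, 6)
  maps <- lapply(1:12, function(i)
    brain_vol(array(rnorm(prod(shape), sd = 1e-3) + 5, shape)))
  fit <- estimate_smoothness(
    fit_group_glm(maps, data.frame(group = rep(0:1, 6)), full_mask(shape)))
  fit$t$data[] <- 0
  expect_equal(nrow(grf_cluster_correct(fit)), 0)
})

test_that("summary-statistic t tests reproduce the cohort table", {
  # printed signs correspond to control minus patient summaries
  hamd <- demographic_t(2.00, 2.10, 32, 23.44, 7.60, 34, "welch")
  expect_equal(hamd$t, -15.83, tolerance = 0.05 / 15.83)
  hdmd <- demographic_t(2.28, 2.82, 32, 18.29, 7.75, 34, "welch")
  expect_equal(hdmd$t, -11.278, tolerance = 0.01 / 11.278)
  fd <- demographic_t(0.51, 0.16, 32, 0.62, 0.31, 34, "pooled")
  expect_equal(fd$t, -1.794, tolerance = 0.01 / 1.794)
  expect_gt(fd$p, 0.05)
})

test_that("t-test properties: equal means, Welch df bounds, degenerate input", {
  expect_equal(demographic_t(5, 1, 10, 5, 2, 12, "pooled")$t, 0)
  expect_equal(demographic_t(5, 1, 10, 5, 2, 12, "welch")$t, 0)
  set.seed(16)
  for (i in 1:20) {
    n1 <- sample(3:40, 1)
    n2 <- sample(3:40, 1)
    w <- demographic_t(rnorm(1), runif(1, 0.1, 3), n1,
                       rnorm(1), runif(1, 0.1, 3), n2, "welch")
    expect_gte(w$df, min(n1, n2) - 1 - 1e-9)
    expect_lte(w$df, n1 + n2 - 2 + 1e-9)
  }
  expect_error(demographic_t(1, 0, 5, 2, 0, 5), "variance")
})

test_that("raw-data t test picks the variant by a variance gate", {
  set.seed(17)
  x <- rnorm(40, sd = 1)
  y <- rnorm(40, sd = 6)
  expect_equal(demographic_t_raw(x, y, "auto")$variant, "welch")
  y2 <- rnorm(40, sd = 1)
  expect_equal(demographic_t_raw(x, y2, "auto")$variant, "pooled")
})

test_that("the 2x2 chi-squared matches the cohort sex table and the oracle", {
  sex <- chi_square_2x2(8, 26, 6, 26)
  expect_equal(sex$chisq, 0.225, tolerance = 0.005 / 0.225)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$chisq, 0)
  # brute-force expected-count oracle on random tables
  set.seed(18)
  for (i in 1:10) {
    tab <- matrix(sample(1:50, 4, replace = TRUE), 2, 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    oracle <- sum((tab - expected)^2 / expected)
    got <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$chisq
    expect_equal(got, oracle, tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(0, 0, 3, 4), "marginal")
})
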