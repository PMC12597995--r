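test_that("regional summarization matches a direct grouping oracle", {
  atlas <- synthetic_atlas(c(8, 8, 6), 12, 3)
  set.seed(20)
  arr <- array(rnorm(prod(c(8, 8, 6))), c(8, 8, 6))
  rv <- regionalize_effect_map(brain_vol(arr, voxel_size = 3), atlas)
  lab <- vol_data(atlas$labels)
  for (rid in atlas$regions$region_id) {
    expect_equal(rv$value[rv$region_id == rid], mean(arr[lab == rid]),
                 tolerance = 1e-12)
  }
  # constant map -> constant vector; impulse -> single nonzero region
  const <- regionalize_effect_map(brain_vol(array(2, c(8, 8, 6)),
                                            voxel_size = 3), atlas)
  expect_true(all(const$value == 2))
  imp <- array(0, c(8, 8, 6))
  vox <- which(lab == 5L)[1]
  imp[vox] <- 7
  rv_imp <- regionalize_effect_map(brain_vol(imp, voxel_size = 3), atlas)
  expect_true(all(rv_imp$value[rv_imp$region_id != 5L] == 0))
  expect_gt(rv_imp$value[rv_imp$region_id == 5L], 0)
})

test_that("PLS1 weights equal the first cross-covariance singular vector", {
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(rnorm(50), 10, 5)
    y <- rnorm(10)
    res <- fit_pls1(x, y)
    xs <- scale(x)
    sv <- svd(crossprod(xs, y - mean(y)))
    w <- sv$u[, 1]
    if (cor(as.numeric(xs %*% w), y) < 0) w <- -w
    expect_equal(unname(res$weights), w, tolerance = 1e-10)
    expect_equal(sqrt(sum(res$weights^2)), 1, tolerance = 1e-12)
    expect_equal(res$scores$value,
                 as.numeric(xs %*% unname(res$weights)), tolerance = 1e-10)
  }
})

test_that("PLS1 attains r = 1 in the noise-free single-factor limit", {
  set.seed(22)
  latent <- rnorm(15)
  x <- outer(latent, rnorm(6))
  expect_equal(fit_pls1(x, latent)$r, 1, tolerance = 1e-10)
})

test_that("a gene identical to the map attains the maximum weight", {
  set.seed(23)
  x <- matrix(rnorm(20 * 8), 20, 8)
  y <- as.numeric(scale(x[, 3]))
  res <- fit_pls1(x, y)
  expect_equal(which.max(abs(res$weights)), 3L, ignore_attr = TRUE)
})

test_that("PLS1 is invariant to region order and to a sign flip of y", {
  set.seed(24)
  x <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(1:30, sprintf("g%02d", 1:10)))
  y <- rnorm(30)
  base <- fit_pls1(x, y)
  perm <- sample.int(30)
  shuffled <- fit_pls1(x[perm, ], regional_vector(1:30, y))
  expect_equal(unname(shuffled$weights), unname(base$weights),
               tolerance = 1e-10)
  expect_equal(shuffled$r, base$r, tolerance = 1e-10)
  flipped <- fit_pls1(x, -y)
  expect_equal(flipped$r, base$r, tolerance = 1e-10)
  expect_equal(unname(flipped$weights), -unname(base$weights),
               tolerance = 1e-10)
})

test_that("rows with missing expression or map values are excluded", {
  set.seed(25)
  x <- matrix(rnorm(36), 12, 3)
  x[4, ] <- NA
  y <- rnorm(12)
  y[9] <- NA
  res <- fit_pls1(region_gene_matrix(1:12, c("a", "b", "c"), x),
                  regional_vector(1:12, y))
  expect_identical(res$region_ids, setdiff(1:12, c(4L, 9L)))
  expect_error(fit_pls1(x[1:3, ] * NA, y[1:3]), "3 regions")
  expect_error(fit_pls1(x[1:5, ], rep(1, 5)), "Zero-variance")
})

test_that("permutation p sits on its grid and is seed-deterministic", {
  set.seed(26)
  x <- matrix(rnorm(20 * 15), 20, 15)
  y <- rnorm(20)
  res <- fit_pls1(x, y)
  p1 <- pls_permutation(res, n_perm = 99, seed = 7)$perm$p
  p2 <- pls_permutation(res, n_perm = 99, seed = 7)$perm$p
  expect_identical(p1, p2)
  expect_equal(p1 * 100, round(p1 * 100), tolerance = 1e-12)
  expect_gte(p1, 1 / 100)
})

test_that("small-n permutation p matches exhaustive enumeration", {
  set.seed(27)
  n <- 6
  x <- matrix(rnorm(n * 4), n, 4)
  y <- rnorm(n)
  res <- fit_pls1(x, y)
  perms <- all_permutations(n)
  r_all <- apply(perms, 1, function(idx) imtx:::pls1_core(x, y[idx])$r)
  p_exact <- mean(r_all >= res$r - 1e-12)
  p_mc <- pls_permutation(res, n_perm = 4000, seed = 3)$perm$p
  expect_lt(abs(p_mc - p_exact), 0.015)
})

test_that("bootstrap gene statistics separate loading from noise genes", {
  set.seed(28)
  n <- 40
  latent <- rnorm(n)
  x <- cbind(outer(latent, c(1, -1, 0.8)) +
               matrix(rnorm(n * 3, sd = 0.05), n, 3),
             matrix(rnorm(n * 12), n, 12))
  colnames(x) <- sprintf("g%02d", 1:15)
  res <- pls_bootstrap(fit_pls1(x, latent), n_boot = 500, seed = 5)
  genes <- res$boot$genes
  expect_true(all(abs(genes$z[1:3]) > 5))
  expect_gt(min(abs(genes$z[1:3])), max(abs(genes$z[4:15])))
  # q >= p and BH step-up monotone in the sorted p order
  expect_true(all(genes$q >= genes$p - 1e-15))
  srt <- dplyr::arrange(genes, p)
  expect_true(all(diff(srt$q) >= -1e-15))
  # determinism
  res2 <- pls_bootstrap(fit_pls1(x, latent), n_boot = 500, seed = 5)
  expect_identical(res$boot$genes$z, res2$boot$genes$z)
})

test_that("selection and overlap use the shared universe correctly", {
  set.seed(29)
  n <- 30
  latent <- rnorm(n)
  x <- cbind(outer(latent, runif(5, 0.8, 1.2)) +
               matrix(rnorm(n * 5, sd = 0.1), n, 5),
             matrix(rnorm(n * 20), n, 20))
  colnames(x) <- sprintf("g%02d", 1:25)
  resA <- pls_transcriptomics(x, latent + rnorm(n, sd = 0.2),
                              n_perm = 99, n_boot = 200, seed = 1)
  resB <- pls_transcriptomics(x, latent + rnorm(n, sd = 0.2),
                              n_perm = 99, n_boot = 200, seed = 2)
  ov <- select_and_overlap(resA, resB)
  expect_true(all(ov$overlap$gene_id %in% ov$set_a$gene_id))
  expect_true(all(ov$overlap$gene_id %in% ov$set_b$gene_id))
  # identical results: overlap equals the set and p is minimal
  ov_same <- select_and_overlap(resA, resA)
  expect_identical(ov_same$overlap$gene_id, ov_same$set_a$gene_id)
  k <- nrow(ov_same$set_a)
  expect_equal(ov_same$overlap_p,
               phyper(k - 1, k, 25 - k, k, lower.tail = FALSE))
})

test_that("the overlap p equals an exact hypergeometric tail summation", {
  # the study's reported set sizes: 1128 and 1147 of 11803 with 294 shared
  n_univ <- 11803
  n_a <- 1128
  n_b <- 1147
  k <- 294
  oracle <- sum(vapply(k:min(n_a, n_b), function(i) {
    exp(lchoose(n_a, i) + lchoose(n_univ - n_a, n_b - i) -
          lchoose(n_univ, n_b))
  }, numeric(1)))
  got <- phyper(k - 1, n_a, n_univ - n_a, n_b, lower.tail = FALSE)
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_lt(got, 1e-30)  # far beyond chance overlap (expected ~110)
})

test_that("overlap of independent null selections is near its expectation", {
  set.seed(30)
  n <- 50
  x <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, sprintf("g%02d", 1:40)))
  sizes <- replicate(8, {
    a <- pls_bootstrap(fit_pls1(x, rnorm(n)), n_boot = 150,
                       seed = sample.int(1e6, 1))
    b <- pls_bootstrap(fit_pls1(x, rnorm(n)), n_boot = 150,
                       seed = sample.int(1e6, 1))
    ov <- select_and_overlap(a, b)
    c(nrow(ov$set_a), nrow(ov$set_b), nrow(ov$overlap))
  })
  expected <- mean(sizes[1, ] * sizes[2, ] / 40)
  expect_lt(abs(mean(sizes[3, ]) - expected), 3)
})
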