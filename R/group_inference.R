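#' Voxelwise covariate-adjusted group contrast
#'
#' Fits, at every in-mask voxel, an ordinary-least-squares model
#' `value ~ group + covariates` across subjects and returns the t map for
#' the group indicator together with the residuals needed for smoothness
#' estimation.
#'
#' @param maps List of 3D [brain_vol]s (or arrays), one per subject, on a
#'   common grid.
#' @param design Data frame with one row per subject: a `group` column
#'   (0/1, logical, or two-level factor/character) and any covariate
#'   columns named in `covariates`. Non-numeric covariates are converted
#'   to treatment dummies.
#' @param mask Brain mask.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return A `group_stat_map`: t map, error df, residual matrix, design.
#' @export
fit_group_glm <- function(maps, design, mask, covariates = character()) {
  stopifnot(length(maps) >= 4L)
  arrs <- lapply(maps, vol_data)
  shape <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), shape), logical(1)))) {
    abort("All subject maps must share one grid.")
  }
  m <- as_mask(mask, shape)
  design <- as.data.frame(design)
  if (!"group" %in% names(design)) abort("`design` needs a `group` column.")
  g <- design$group
  if (is.factor(g) || is.character(g)) g <- as.integer(factor(g)) - 1L
  g <- as.numeric(g)
  if (!all(g %in% c(0, 1)) || min(table(g)) < 2) {
    abort("Group must be two-level with at least 2 subjects per group.")
  }
  x <- cbind(intercept = 1, group = g)
  for (cv in covariates) {
    v <- design[[cv]]
    if (is.factor(v) || is.character(v)) {
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
      x <- cbind(x, mm)
    } else {
      x <- cbind(x, setNames(data.frame(as.numeric(v)), cv))
    }
  }
  x <- as.matrix(x)
  if (nrow(x) != length(arrs)) abort("Design rows must match the map list.")
  if (qr(x)$rank < ncol(x)) abort("Design matrix is rank deficient.")

  y <- vapply(arrs, function(a) a[m], numeric(sum(m)))  # voxels x subjects
  y <- t(y)                                             # subjects x voxels
  xtx_inv <- solve(crossprod(x))
  betas <- xtx_inv %*% crossprod(x, y)
  resid <- y - x %*% betas
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(resid^2) / df
  c_var <- xtx_inv["group", "group"]
  se <- sqrt(pmax(sigma2 * c_var, .Machine$double.xmin))
  tvals <- betas["group", ] / se

  tmap <- array(0, dim = shape)
  tmap[m] <- tvals
  bmap <- array(0, dim = shape)
  bmap[m] <- betas["group", ]
  vol1 <- if (is_brain_vol(maps[[1]])) maps[[1]] else brain_vol(arrs[[1]])
  structure(
    list(t = brain_vol(tmap, voxel_size = vol1$voxel_size,
                       affine = vol1$affine, units = "t"),
         beta = brain_vol(bmap, voxel_size = vol1$voxel_size,
                          affine = vol1$affine),
         df = df, mask = m, residuals = resid, design = x,
         smoothness = NULL),
    class = "group_stat_map"
  )
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat("<group_stat_map> df = ", x$df, ", ", sum(x$mask), " in-mask voxels\n",
      sep = "")
  invisible(x)
}

#' Residual smoothness and RESEL count
#'
#' Estimates the per-axis smoothness (FWHM, mm) of the error field from
#' the spatial derivatives of unit-normalized GLM residuals:
#' `lambda = Var(d u / d x)` per axis in voxel units and
#' `FWHM = sqrt(4 log 2 / lambda)`. The RESEL count is the in-mask volume
#' divided by the product of the per-axis FWHMs (voxel units).
#'
#' @param stat A `group_stat_map` from [fit_group_glm()].
#' @return The `group_stat_map` with a `smoothness` element:
#'   `fwhm_mm`, `fwhm_vox`, `resels`, `n_mask`.
#' @export
estimate_smoothness <- function(stat) {
  stopifnot(inherits(stat, "group_stat_map"))
  m <- stat$mask
  shape <- dim(m)
  r <- stat$residuals                       # subjects x voxels (in-mask)
  norms <- sqrt(colSums(r^2))
  ok <- norms > 0
  u <- sweep(r[, ok, drop = FALSE], 2, norms[ok], "/")

  vox_of <- array(NA_integer_, dim = shape)
  vox_of[m][ok] <- seq_len(sum(ok))
  lambda <- numeric(3)
  for (axis in 1:3) {
    idx <- which(!is.na(vox_of), arr.ind = TRUE)
    nb <- idx
    nb[, axis] <- nb[, axis] + 1L
    keep <- nb[, axis] <= shape[axis]
    a <- vox_of[idx[keep, , drop = FALSE]]
    b <- vox_of[nb[keep, , drop = FALSE]]
    pair <- !is.na(a) & !is.na(b)
    if (sum(pair) < 2L) {
      abort(sprintf("Fewer than 2 in-mask neighbour pairs along axis %d.", axis))
    }
    du <- u[, b[pair], drop = FALSE] - u[, a[pair], drop = FALSE]
    lambda[axis] <- mean(colSums(du^2))
  }
  fwhm_vox <- sqrt(4 * log(2) / lambda)
  n_mask <- sum(m)
  stat$smoothness <- list(
    fwhm_vox = fwhm_vox,
    fwhm_mm = fwhm_vox * stat$t$voxel_size,
    resels = n_mask / prod(fwhm_vox),
    n_mask = n_mask
  )
  stat
}

# Expected number of clusters (Euler characteristic density, 3D term) for
# a Gaussian field above z, per excursion tail, times the resel count.
grf_expected_clusters <- function(z, resels) {
  resels * (4 * log(2))^(3 / 2) / (2 * pi)^2 * (z^2 - 1) * exp(-z^2 / 2)
}

#' GRF cluster-level correction
#'
#' Thresholds the |t| map at the two-sided `voxel_p` quantile for the
#' fit's df, forms 26-connected clusters separately in the positive and
#' negative tails, and assigns each cluster a Gaussian-random-field
#' cluster-level corrected p computed from the estimated smoothness. The
#' expected cluster count uses the full two-sided excursion set so the
#' family-wise rate over the whole map is controlled at `cluster_p`.
#'
#' @param stat A `group_stat_map` with smoothness estimated (or it is
#'   estimated on the fly).
#' @param voxel_p Two-sided voxel-level threshold (default 0.001).
#' @param cluster_p Cluster-level corrected threshold (default 0.05).
#' @param all_clusters Return every cluster (surviving or not) with a
#'   `survives` column instead of only the surviving ones.
#' @return Tibble of cluster records: `cluster_id`, `sign`, `n_voxels`,
#'   `peak_t`, `peak_x/y/z` (mm), `p_corrected`, ordered by p. Empty when
#'   nothing crosses the voxel threshold.
#' @export
grf_cluster_correct <- function(stat, voxel_p = 0.001, cluster_p = 0.05,
                                all_clusters = FALSE) {
  stopifnot(inherits(stat, "group_stat_map"))
  if (is.null(stat$smoothness)) stat <- estimate_smoothness(stat)
  sm <- stat$smoothness
  u_t <- qt(1 - voxel_p / 2, df = stat$df)
  z_u <- qnorm(1 - voxel_p / 2)
  e_clusters <- 2 * grf_expected_clusters(z_u, sm$resels)
  e_voxels <- sm$n_mask * 2 * pnorm(-z_u)
  beta <- (gamma(5 / 2) * max(e_clusters, .Machine$double.xmin) /
             max(e_voxels, .Machine$double.xmin))^(2 / 3)

  tarr <- vol_data(stat$t)
  recs <- list()
  for (sgn in c(1, -1)) {
    supra <- (sgn * tarr > u_t) & stat$mask
    if (!any(supra)) next
    comp <- connected_components(supra)
    for (ci in seq_along(comp)) {
      vox <- comp[[ci]]
      k <- length(vox)
      peak <- vox[which.max(sgn * tarr[vox])]
      ijk <- arrayInd(peak, dim(tarr)) - 1L
      mm <- vox_to_mm(stat$t$affine, ijk)
      p_unc <- exp(-beta * k^(2 / 3))
      p_cor <- 1 - exp(-e_clusters * p_unc)
      recs[[length(recs) + 1L]] <- tibble(
        sign = if (sgn > 0) "positive" else "negative",
        n_voxels = k, peak_t = tarr[peak],
        peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        p_corrected = p_cor,
        voxels = list(vox)
      )
    }
  }
  out <- if (length(recs)) dplyr::bind_rows(recs) else
    tibble(sign = character(), n_voxels = integer(), peak_t = numeric(),
           peak_x = numeric(), peak_y = numeric(), peak_z = numeric(),
           p_corrected = numeric(), voxels = list())
  out <- dplyr::arrange(out, .data$p_corrected, dplyr::desc(.data$n_voxels))
  out$survives <- out$p_corrected < cluster_p
  out$cluster_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "cluster_id")
  if (!all_clusters) out <- dplyr::filter(out, .data$survives)
  out
}

# 26-connected components of a logical 3D array; returns a list of
# linear-index vectors.
connected_components <- function(supra) {
  shape <- dim(supra)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  remaining <- array(supra, dim = shape)
  comps <- list()
  seeds <- which(remaining)
  for (s in seeds) {
    if (!remaining[s]) next
    queue <- s
    remaining[s] <- FALSE
    members <- integer()
    while (length(queue)) {
      cur <- queue
      queue <- integer()
      members <- c(members, cur)
      ijk <- arrayInd(cur, shape)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(ijk, 2, offs[o, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= shape[3]
        if (!any(ok)) next
        lin <- nb[ok, 1, drop = TRUE] +
          (nb[ok, 2, drop = TRUE] - 1L) * shape[1] +
          (nb[ok, 3, drop = TRUE] - 1L) * shape[1] * shape[2]
        hit <- lin[remaining[lin]]
        if (length(hit)) {
          remaining[hit] <- FALSE
          queue <- c(queue, hit)
        }
      }
      queue <- unique(queue)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' Two-sample t test from summary statistics
#'
#' Computes the Student (pooled-variance) or Welch t statistic from group
#' means, SDs and sizes. The sign is `group1 - group2` as supplied.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return Tibble with `t`, `df`, `p` (two-sided), `variant`.
#' @export
demographic_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                          variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) abort("Zero variance in both groups.")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- (mean1 - mean2) / se
  tibble(t = tval, df = df, p = 2 * pt(-abs(tval), df), variant = variant)
}

#' Two-sample t test on raw data with a variance-equality gate
#'
#' `variant = "auto"` runs Levene's test (absolute deviations from group
#' means, the convention of common statistics packages) at alpha = 0.05
#' and picks pooled when equal variances are tenable, Welch otherwise.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param variant `"auto"`, `"pooled"` or `"welch"`.
#' @return Tibble with `t`, `df`, `p`, `variant` (the one used).
#' @export
demographic_t_raw <- function(x, y, variant = c("auto", "pooled", "welch")) {
  variant <- match.arg(variant)
  if (variant == "auto") {
    lev <- stats::t.test(abs(x - mean(x)), abs(y - mean(y)), var.equal = TRUE)
    variant <- if (lev$p.value < 0.05) "welch" else "pooled"
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, variant = variant)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' No continuity correction, matching the convention used for the
#' sex-by-group comparison.
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = categories
#'   (`a b / c d`).
#' @return Tibble with `chisq`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("A zero row or column marginal makes the test undefined.")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(chisq = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}
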