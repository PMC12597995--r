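#' Summarize a voxel map over atlas regions
#'
#' Region value = mean in-mask voxel value within the region. Regions
#' with no in-mask voxel get `NA`.
#'
#' @param tmap 3D [brain_vol] (typically a t map).
#' @param atlas A [parcellation_atlas] on the same grid.
#' @param mask Optional mask restricting the voxels averaged.
#' @return A [regional_vector] tibble over the atlas region table order.
#' @export
regionalize_effect_map <- function(tmap, atlas, mask = NULL) {
  arr <- vol_data(tmap)
  lab <- vol_data(atlas$labels)
  if (!identical(dim(arr), dim(lab))) abort("Map and atlas grids differ.")
  rvi <- region_voxel_index(atlas, mask)
  vals <- vapply(as.character(atlas$regions$region_id), function(id) {
    v <- rvi[[id]]
    if (is.null(v) || !length(v)) NA_real_ else mean(arr[v])
  }, numeric(1))
  regional_vector(atlas$regions$region_id, vals)
}

# Column z-scoring with zero-variance columns mapped to 0.
standardize_columns <- function(xmat) {
  n <- nrow(xmat)
  mu <- colMeans(xmat)
  sdv <- sqrt(pmax(colSums(xmat^2) - n * mu^2, 0) / (n - 1))
  xs <- sweep(xmat, 2, mu, "-")
  nz <- sdv > 0
  xs[, nz] <- sweep(xs[, nz, drop = FALSE], 2, sdv[nz], "/")
  xs[, !nz] <- 0
  xs
}

# Core PLS1 fit on an aligned numeric matrix and response: z-score the
# columns (zero-variance columns get zero weight), centre y, first
# component weights proportional to X'y, sign fixed so cor(scores, y) >= 0.
pls1_core <- function(xmat, yvec) {
  xs <- standardize_columns(xmat)
  yc <- yvec - mean(yvec)
  w <- as.numeric(crossprod(xs, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) {
    w <- rep(0, ncol(xmat))
    return(list(weights = w, scores = rep(0, nrow(xmat)), r = 0))
  }
  w <- w / nw
  s <- as.numeric(xs %*% w)
  r <- if (sd(s) == 0) 0 else cor(s, yvec)
  if (r < 0) {
    w <- -w
    s <- -s
    r <- -r
  }
  list(weights = w, scores = s, r = r)
}

#' First-component PLS between expression and a regional map
#'
#' Computes the first partial-least-squares component relating the
#' region-by-gene expression matrix (columns z-scored across regions) to
#' a centred regional phenotype map: unit-norm gene weights proportional
#' to the gene-map cross-covariance, region scores `X w`, and the spatial
#' Pearson correlation `r` between scores and map. The sign is fixed so
#' `r >= 0`.
#'
#' @param x A [region_gene_matrix] (or plain regions x genes matrix with
#'   gene column names and region row names).
#' @param y A [regional_vector] (or numeric vector aligned to `x` rows).
#' @return A `pls_result` with `weights`, `scores`, `r`, and the aligned
#'   data for resampling inference.
#' @export
fit_pls1 <- function(x, y) {
  if (inherits(x, "region_gene_matrix")) {
    xmat <- x$values
    x_regions <- x$region_ids
    gene_ids <- x$gene_ids
  } else {
    xmat <- as.matrix(x)
    x_regions <- if (is.null(rownames(xmat))) seq_len(nrow(xmat)) else
      as.integer(rownames(xmat))
    gene_ids <- colnames(xmat)
    if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(ncol(xmat)))
  }
  if (is.data.frame(y)) {
    yv <- setNames(y$value, y$region_id)[as.character(x_regions)]
  } else if (length(y) == nrow(xmat)) {
    yv <- as.numeric(y)
  } else {
    abort("`y` must align with the rows of `x`.")
  }
  keep <- rowSums(is.na(xmat)) == 0 & !is.na(yv)
  xmat <- xmat[keep, , drop = FALSE]
  yv <- yv[keep]
  regions <- x_regions[keep]
  if (nrow(xmat) < 3L) abort("Need at least 3 regions common to `x` and `y`.")
  if (sd(yv) == 0) abort("Zero-variance regional map.")
  fit <- pls1_core(xmat, yv)
  structure(
    list(weights = setNames(fit$weights, gene_ids),
         scores = regional_vector(regions, fit$scores),
         r = fit$r, gene_ids = gene_ids, region_ids = regions,
         x = xmat, y = yv,
         perm = NULL, boot = NULL, alpha = NULL),
    class = "pls_result"
  )
}

#' @export
print.pls_result <- function(x, ...) {
  cat("<pls_result> ", length(x$region_ids), " regions x ",
      length(x$gene_ids), " genes; spatial r = ", signif(x$r, 4), sep = "")
  if (!is.null(x$perm)) cat(", permutation p = ", signif(x$perm$p, 3), sep = "")
  if (!is.null(x$boot)) cat("; bootstrap over ", x$boot$n_boot, " draws",
                            sep = "")
  cat("\n")
  invisible(x)
}

#' Permutation test of the PLS spatial correlation
#'
#' Refits PLS1 on region-shuffled maps and reports the one-sided
#' permutation p of the observed `r`, with the add-one convention
#' `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)` so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param result A `pls_result` from [fit_pls1()].
#' @param n_perm Number of permutations (default 10000, giving a p floor
#'   of about 1e-4).
#' @param seed Integer seed.
#' @return The `pls_result` with a `perm` element (`p`, `r_null`,
#'   `n_perm`, `seed`).
#' @export
pls_permutation <- function(result, n_perm = 10000, seed = 1L) {
  stopifnot(inherits(result, "pls_result"), n_perm >= 1)
  n <- length(result$y)
  # X is unchanged by permuting y, so standardize once and evaluate the
  # refit for blocks of permutations with two matrix products.
  xs <- standardize_columns(result$x)
  r_null <- with_seed(seed, {
    perm_idx <- replicate(n_perm, sample.int(n))
    out <- numeric(n_perm)
    for (start in seq(1, n_perm, by = 2000L)) {
      cols <- start:min(start + 1999L, n_perm)
      yp <- matrix(result$y[perm_idx[, cols]], n, length(cols))
      ypc <- sweep(yp, 2, colMeans(yp), "-")
      w <- crossprod(xs, ypc)
      wn <- sqrt(colSums(w^2))
      s <- xs %*% sweep(w, 2, pmax(wn, .Machine$double.xmin), "/")
      sc <- sweep(s, 2, colMeans(s), "-")
      num <- colSums(sc * ypc)
      den <- sqrt(colSums(sc^2) * colSums(ypc^2))
      r <- abs(num) / pmax(den, .Machine$double.xmin)
      r[wn == 0 | den == 0] <- 0
      out[cols] <- r
    }
    out
  })
  p <- (1 + sum(r_null >= result$r - 1e-12)) / (1 + n_perm)
  result$perm <- list(p = p, r_null = r_null, n_perm = n_perm, seed = seed)
  result
}

#' Bootstrap z-scores for PLS gene weights
#'
#' Resamples regions with replacement, refits PLS1, aligns each
#' replicate's weight sign with the original weights (sign of their dot
#' product), and reports `z = w / SD_boot(w)` per gene with two-sided
#' normal p and Benjamini-Hochberg q over all genes.
#'
#' @param result A `pls_result`.
#' @param n_boot Number of bootstrap draws (default 5000).
#' @param seed Integer seed.
#' @param max_redraw Cap on redraws of degenerate resamples (constant
#'   map); exceeding it is an error.
#' @return The `pls_result` with a `boot` element whose `genes` tibble
#'   has `gene_id`, `weight`, `z`, `p`, `q`.
#' @export
pls_bootstrap <- function(result, n_boot = 5000, seed = 1L,
                          max_redraw = 100L) {
  stopifnot(inherits(result, "pls_result"), n_boot >= 100)
  n <- length(result$y)
  w0 <- unname(result$weights)
  wboot <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, length(w0))
    redraws <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(result$y[idx]) > 0) break
        redraws <- redraws + 1L
        if (redraws > max_redraw) {
          abort("Too many degenerate bootstrap resamples (constant map).")
        }
      }
      wb <- pls1_core(result$x[idx, , drop = FALSE], result$y[idx])$weights
      if (sum(wb * w0) < 0) wb <- -wb
      out[b, ] <- wb
    }
    out
  })
  sd_w <- apply(wboot, 2, sd)
  z <- w0 / sd_w
  z[sd_w == 0] <- 0
  p <- 2 * pnorm(-abs(z))
  genes <- tibble(gene_id = result$gene_ids, weight = w0, z = z, p = p,
                  q = p.adjust(p, method = "BH"))
  result$boot <- list(genes = genes, n_boot = n_boot, seed = seed)
  result
}

#' Fit, test and bootstrap a PLS association in one call
#'
#' @param x,y As in [fit_pls1()].
#' @param n_perm,n_boot Resampling sizes.
#' @param seed Integer seed (permutation uses `seed`, bootstrap
#'   `seed + 1`).
#' @param alpha Gene selection threshold on the bootstrap p.
#' @return A `pls_result` with `perm`, `boot`, and `selected` (gene IDs
#'   with bootstrap `p < alpha`).
#' @export
pls_transcriptomics <- function(x, y, n_perm = 10000, n_boot = 5000,
                                seed = 1L, alpha = 0.05) {
  res <- fit_pls1(x, y)
  res <- pls_permutation(res, n_perm = n_perm, seed = seed)
  res <- pls_bootstrap(res, n_boot = n_boot, seed = seed + 1L)
  res$alpha <- alpha
  res$selected <- res$boot$genes$gene_id[res$boot$genes$p < alpha]
  res
}

#' @describeIn fit_pls1 Per-gene tibble (`gene_id`, `weight`, and — after
#'   [pls_bootstrap()] — `z`, `p`, `q`).
#' @param x A `pls_result`.
#' @param ... Unused.
#' @method tidy pls_result
#' @export
tidy.pls_result <- function(x, ...) {
  if (!is.null(x$boot)) return(x$boot$genes)
  tibble(gene_id = x$gene_ids, weight = unname(x$weights))
}

#' @describeIn fit_pls1 One-row model summary (`n_regions`, `n_genes`,
#'   `r`, `perm_p`, `n_selected`).
#' @method glance pls_result
#' @export
glance.pls_result <- function(x, ...) {
  tibble(n_regions = length(x$region_ids), n_genes = length(x$gene_ids),
         r = x$r,
         perm_p = if (is.null(x$perm)) NA_real_ else x$perm$p,
         n_selected = if (is.null(x$selected)) NA_integer_ else
           length(x$selected))
}

#' Select per-map gene sets and test their overlap
#'
#' Genes with bootstrap `p < alpha` form each map's set; the overlap is
#' their intersection, with a one-sided hypergeometric tail p for an
#' overlap at least as large given the shared gene universe.
#'
#' @param res_a,res_b Bootstrapped `pls_result`s over the same universe.
#' @param alpha Selection threshold (default 0.05).
#' @param tag_a,tag_b Provenance tags for the two sets.
#' @return List with `set_a`, `set_b`, `overlap` (tibbles of `gene_id`
#'   and `provenance`), and `overlap_p`.
#' @export
select_and_overlap <- function(res_a, res_b, alpha = 0.05,
                               tag_a = "ALFF", tag_b = "CBF") {
  stopifnot(inherits(res_a, "pls_result"), inherits(res_b, "pls_result"))
  if (is.null(res_a$boot) || is.null(res_b$boot)) {
    abort("Both results need bootstrap gene statistics.")
  }
  if (!identical(sort(res_a$gene_ids), sort(res_b$gene_ids))) {
    abort("The two results must share one gene universe.")
  }
  sel <- function(res) res$boot$genes$gene_id[res$boot$genes$p < alpha]
  a <- sel(res_a)
  b <- sel(res_b)
  ov <- intersect(a, b)
  n_univ <- length(res_a$gene_ids)
  overlap_p <- phyper(length(ov) - 1, length(a), n_univ - length(a),
                      length(b), lower.tail = FALSE)
  list(set_a = tibble(gene_id = a, provenance = tag_a),
       set_b = tibble(gene_id = b, provenance = tag_b),
       overlap = tibble(gene_id = ov, provenance = "overlap"),
       overlap_p = overlap_p,
       universe = sort(res_a$gene_ids))
}
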