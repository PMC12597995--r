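#' Region-by-gene expression matrix
#'
#' Rows are atlas regions, columns genes. A region sampled by no donor
#' sample is an all-`NA` row (absent, never zero), forcing explicit
#' missing-data handling downstream.
#'
#' @param region_ids Ordered integer region IDs (unique).
#' @param gene_ids Ordered character gene IDs (unique).
#' @param values Numeric matrix `length(region_ids) x length(gene_ids)`.
#' @return A `region_gene_matrix`.
#' @export
region_gene_matrix <- function(region_ids, gene_ids, values) {
  values <- as.matrix(values)
  region_ids <- as.integer(region_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(region_ids)) abort("Duplicate region IDs.")
  if (anyDuplicated(gene_ids)) abort("Duplicate gene IDs.")
  if (!all(dim(values) == c(length(region_ids), length(gene_ids)))) {
    abort("`values` must be regions x genes.")
  }
  dimnames(values) <- list(region_ids, gene_ids)
  structure(list(region_ids = region_ids, gene_ids = gene_ids,
                 values = values),
            class = "region_gene_matrix")
}

#' @export
print.region_gene_matrix <- function(x, ...) {
  cat("<region_gene_matrix> ", length(x$region_ids), " regions x ",
      length(x$gene_ids), " genes (", sum(rowSums(!is.na(x$values)) == 0),
      " missing regions)\n", sep = "")
  invisible(x)
}

#' @method as_tibble region_gene_matrix
#' @export
as_tibble.region_gene_matrix <- function(x, ...) {
  dplyr::bind_cols(tibble(region_id = x$region_ids),
                   as_tibble(x$values, .name_repair = "minimal"))
}

missing_regions <- function(x) {
  x$region_ids[rowSums(!is.na(x$values)) == 0]
}

#' Donor expression sample set
#'
#' @param donor_id Donor label.
#' @param coords Numeric `n x 3` matrix of sample MNI coordinates (mm).
#' @param expr Numeric `n x genes` expression matrix.
#' @param gene_ids Character gene IDs.
#' @return A `donor_expression`.
#' @export
donor_expression <- function(donor_id, coords, expr, gene_ids) {
  coords <- as.matrix(coords)
  expr <- as.matrix(expr)
  stopifnot(ncol(coords) == 3, nrow(coords) == nrow(expr),
            ncol(expr) == length(gene_ids), all(is.finite(coords)))
  structure(list(donor_id = donor_id, coords = coords, expr = expr,
                 gene_ids = as.character(gene_ids)),
            class = "donor_expression")
}

#' Assign donor samples to atlas regions
#'
#' Each sample is assigned to the region of the labelled voxel nearest
#' its MNI coordinate, provided that voxel lies within `tolerance_mm`;
#' samples farther from any labelled voxel are dropped. A region's value
#' is the mean over its assigned samples; regions receiving no sample are
#' missing rows.
#'
#' @param donor A [donor_expression].
#' @param atlas A [parcellation_atlas].
#' @param tolerance_mm Maximum sample-to-voxel-centre distance (default
#'   2 mm, the common toolbox default).
#' @return A [region_gene_matrix] over the atlas's region table order.
#' @export
assign_samples <- function(donor, atlas, tolerance_mm = 2) {
  stopifnot(inherits(donor, "donor_expression"),
            inherits(atlas, "parcellation_atlas"), tolerance_mm >= 0)
  lab <- vol_data(atlas$labels)
  lab_idx <- which(lab > 0L)
  lab_ijk <- arrayInd(lab_idx, dim(lab)) - 1L
  lab_mm <- vox_to_mm(atlas$labels$affine, lab_ijk)
  lab_region <- lab[lab_idx]

  n <- nrow(donor$coords)
  assigned <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (lab_mm[, 1] - donor$coords[i, 1])^2 +
      (lab_mm[, 2] - donor$coords[i, 2])^2 +
      (lab_mm[, 3] - donor$coords[i, 3])^2
    j <- which.min(d2)
    assigned[i] <- if (sqrt(d2[j]) <= tolerance_mm) lab_region[j] else 0L
  }
  if (!any(assigned > 0L)) {
    abort(sprintf("No sample of donor %s lies within %g mm of a labelled voxel.",
                  donor$donor_id, tolerance_mm))
  }
  region_ids <- atlas$regions$region_id
  vals <- matrix(NA_real_, length(region_ids), length(donor$gene_ids))
  for (ri in seq_along(region_ids)) {
    rows <- which(assigned == region_ids[ri])
    if (length(rows)) {
      vals[ri, ] <- colMeans(donor$expr[rows, , drop = FALSE])
    }
  }
  region_gene_matrix(region_ids, donor$gene_ids, vals)
}

# Columnwise Pearson correlations between matching columns of two
# matrices over rows present in both.
paired_column_cor <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a), "-")
  bc <- sweep(b, 2, colMeans(b), "-")
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Inter-donor gene stability filter
#'
#' For every gene, computes the Pearson correlation of its regional
#' profile between each donor pair over their shared non-missing regions,
#' and retains genes whose mean pairwise correlation exceeds `threshold`
#' (strictly). Donor pairs sharing fewer than 3 regions are skipped; a
#' gene with no valid pair is dropped.
#'
#' @param matrices List of per-donor [region_gene_matrix] objects with a
#'   common gene set and region order.
#' @param threshold Retention threshold on the mean pairwise correlation
#'   (default 0.1, strict inequality).
#' @return Character vector of retained gene IDs (input order).
#' @export
filter_stable_genes <- function(matrices, threshold = 0.1) {
  stopifnot(length(matrices) >= 2L)
  gene_ids <- matrices[[1]]$gene_ids
  for (m in matrices) {
    if (!identical(m$gene_ids, gene_ids)) abort("Donors must share one gene set.")
    if (!identical(m$region_ids, matrices[[1]]$region_ids)) {
      abort("Donors must share one region order.")
    }
  }
  present <- vapply(matrices, function(m) rowSums(!is.na(m$values)) > 0,
                    logical(length(matrices[[1]]$region_ids)))
  nd <- length(matrices)
  sum_r <- numeric(length(gene_ids))
  n_pair <- numeric(length(gene_ids))
  for (i in seq_len(nd - 1)) for (j in (i + 1):nd) {
    shared <- which(present[, i] & present[, j])
    if (length(shared) < 3L) next
    r <- paired_column_cor(matrices[[i]]$values[shared, , drop = FALSE],
                           matrices[[j]]$values[shared, , drop = FALSE])
    ok <- !is.na(r)
    sum_r[ok] <- sum_r[ok] + r[ok]
    n_pair[ok] <- n_pair[ok] + 1
  }
  mean_r <- ifelse(n_pair > 0, sum_r / n_pair, -Inf)
  gene_ids[mean_r > threshold]
}

normalize_gene_profiles <- function(values,
                                    method = c("robust_sigmoid", "zscore",
                                               "none")) {
  method <- match.arg(method)
  if (method == "none") return(values)
  apply(values, 2, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2) return(v)
    if (method == "zscore") {
      s <- sd(v[ok])
      if (s == 0) v[ok] <- 0 else v[ok] <- (v[ok] - mean(v[ok])) / s
      return(v)
    }
    # scaled robust sigmoid: sigmoid with median / normalized IQR, then
    # min-max rescale to [0, 1]
    med <- median(v[ok])
    iqr <- stats::IQR(v[ok]) / 1.349
    if (iqr == 0) iqr <- sd(v[ok])
    if (iqr == 0) {
      v[ok] <- 0.5
      return(v)
    }
    s <- 1 / (1 + exp(-(v[ok] - med) / iqr))
    rng <- range(s)
    v[ok] <- if (diff(rng) == 0) 0.5 else (s - rng[1]) / diff(rng)
    v
  })
}

#' Average donors into one region-by-gene matrix
#'
#' Applies a per-donor, per-gene normalization across regions and then
#' averages donors element-wise, ignoring missing rows. Regions missing
#' in every donor are dropped.
#'
#' @param matrices List of per-donor [region_gene_matrix] objects.
#' @param retained_genes Character vector of gene IDs to keep (e.g. from
#'   [filter_stable_genes()]); order is preserved in the output.
#' @param normalization `"robust_sigmoid"` (default), `"zscore"`, or
#'   `"none"`.
#' @return A [region_gene_matrix].
#' @export
combine_donors <- function(matrices, retained_genes,
                           normalization = c("robust_sigmoid", "zscore",
                                             "none")) {
  normalization <- match.arg(normalization)
  stopifnot(length(matrices) >= 1L)
  if (!length(retained_genes)) abort("Empty retained gene set.")
  for (m in matrices) {
    if (!all(retained_genes %in% m$gene_ids)) {
      abort("retained_genes must be present in every donor.")
    }
  }
  region_ids <- matrices[[1]]$region_ids
  acc <- matrix(0, length(region_ids), length(retained_genes))
  cnt <- matrix(0, length(region_ids), length(retained_genes))
  for (m in matrices) {
    vals <- m$values[, retained_genes, drop = FALSE]
    vals <- normalize_gene_profiles(vals, normalization)
    ok <- !is.na(vals)
    vals[!ok] <- 0
    acc <- acc + vals
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  keep <- rowSums(!is.na(out)) > 0
  region_gene_matrix(region_ids[keep], retained_genes,
                     out[keep, , drop = FALSE])
}

#' Build the donor-averaged expression matrix in one call
#'
#' Convenience wrapper: assign samples (when donors carry coordinates),
#' stability-filter, and average.
#'
#' @param donors List of [donor_expression] sets or of per-donor
#'   [region_gene_matrix] objects.
#' @param atlas [parcellation_atlas]; required for coordinate input.
#' @param stability_threshold Mean pairwise correlation cutoff.
#' @param tolerance_mm Sample assignment tolerance.
#' @param normalization Passed to [combine_donors()].
#' @return List with `matrix` ([region_gene_matrix]), `retained_genes`,
#'   and `donor_matrices`.
#' @export
build_expression_matrix <- function(donors, atlas = NULL,
                                    stability_threshold = 0.1,
                                    tolerance_mm = 2,
                                    normalization = "robust_sigmoid") {
  mats <- lapply(donors, function(d) {
    if (inherits(d, "region_gene_matrix")) return(d)
    if (inherits(d, "donor_expression")) {
      if (is.null(atlas)) abort("Coordinate donors need an atlas.")
      return(assign_samples(d, atlas, tolerance_mm))
    }
    abort("Each donor must be a donor_expression or region_gene_matrix.")
  })
  retained <- filter_stable_genes(mats, stability_threshold)
  if (!length(retained)) abort("No gene passed the stability filter.")
  list(matrix = combine_donors(mats, retained, normalization),
       retained_genes = retained, donor_matrices = mats)
}
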