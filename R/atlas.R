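#' Parcellation atlas
#'
#' An integer-labelled volume plus a region table. Label 0 is background;
#' every positive label in the grid must appear in the region table.
#'
#' @param labels A [brain_vol] (or 3D array) of integer region labels.
#' @param regions A data frame with columns `region_id` (positive integers,
#'   unique), `name`, and optionally `source`.
#' @return An object of class `parcellation_atlas`.
#' @export
parcellation_atlas <- function(labels, regions) {
  if (!is_brain_vol(labels)) labels <- brain_vol(labels)
  lab <- vol_data(labels)
  if (length(dim(lab)) != 3L) abort("Atlas labels must be a 3D grid.")
  storage.mode(lab) <- "integer"
  labels$data <- lab
  regions <- as_tibble(regions)
  if (!all(c("region_id", "name") %in% names(regions))) {
    abort("`regions` needs columns region_id and name.")
  }
  if (!("source" %in% names(regions))) regions$source <- NA_character_
  regions$region_id <- as.integer(regions$region_id)
  if (anyDuplicated(regions$region_id) || any(regions$region_id <= 0)) {
    abort("region_id values must be unique positive integers.")
  }
  used <- setdiff(unique(as.vector(lab)), 0L)
  if (!all(used %in% regions$region_id)) {
    abort("Grid contains labels absent from the region table.")
  }
  structure(list(labels = labels, regions = regions),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat("<parcellation_atlas> ", nrow(x$regions), " regions on a ",
      paste(dim(x$labels$data), collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Build a block parcellation for simulation
#'
#' Partitions a rectangular grid into near-cubic contiguous blocks and
#' labels the first `n_regions` of them as regions (remaining blocks are
#' background). Region effects injected on this support are exactly
#' scorable at the region level.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param n_regions Number of regions to label.
#' @param voxel_size mm per axis (scalar or length 3).
#' @return A [parcellation_atlas].
#' @export
synthetic_atlas <- function(grid_shape, n_regions, voxel_size = 3) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L), n_regions >= 1)
  splits <- block_splits(grid_shape, n_regions)
  cuts <- lapply(1:3, function(a) {
    sort(rep_len(seq_len(splits[a]), grid_shape[a]))
  })
  block_id <- array(0L, dim = grid_shape)
  # row-major over (bx, by, bz) so consecutive ids tile the volume
  idx <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3])))
  b <- (cuts[[3]][idx[, 3]] - 1L) * splits[1] * splits[2] +
    (cuts[[2]][idx[, 2]] - 1L) * splits[1] + cuts[[1]][idx[, 1]]
  b[b > n_regions] <- 0L
  block_id[idx] <- b
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  parcellation_atlas(
    brain_vol(block_id, voxel_size = voxel_size),
    tibble(region_id = seq_len(n_regions),
           name = sprintf("R%03d", seq_len(n_regions)),
           source = "synthetic")
  )
}

block_splits <- function(grid_shape, n_regions) {
  base <- max(1L, floor(n_regions^(1 / 3)))
  best <- NULL
  for (s1 in base:(base + 2L)) for (s2 in base:(base + 2L)) {
    s3 <- ceiling(n_regions / (s1 * s2))
    s <- c(s1, s2, s3)
    if (any(s > grid_shape)) next
    waste <- prod(s) - n_regions
    if (is.null(best) || waste < best$waste) best <- list(s = s, waste = waste)
  }
  if (is.null(best)) abort("Grid too small for the requested region count.")
  best$s
}

#' Region-indexed vector
#'
#' @param region_id Integer region IDs.
#' @param value Numeric values, one per region.
#' @return A tibble with columns `region_id`, `value`.
#' @export
regional_vector <- function(region_id, value) {
  stopifnot(length(region_id) == length(value))
  tibble(region_id = as.integer(region_id), value = as.numeric(value))
}

# Per-region voxel index list for an atlas restricted to a mask.
region_voxel_index <- function(atlas, mask = NULL) {
  lab <- vol_data(atlas$labels)
  keep <- lab > 0L
  if (!is.null(mask)) keep <- keep & as_mask(mask, dim(lab))
  split(which(keep), lab[keep])
}
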