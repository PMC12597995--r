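#' Volumetric brain image
#'
#' A light container for a 3D or 4D voxel grid in a known physical space:
#' the data array, per-axis voxel size in mm, a 4x4 voxel-to-world (MNI mm)
#' affine, and — for 4D series — the repetition time in seconds.
#'
#' @param data Numeric array, 3D (`X x Y x Z`) or 4D (`X x Y x Z x T`).
#' @param voxel_size Numeric length-3, mm per axis; all entries must be > 0.
#' @param affine Optional 4x4 voxel-to-mm transform (0-based voxel indices).
#'   Defaults to a diagonal scaling by `voxel_size` with the grid centre at
#'   the origin.
#' @param tr Repetition time in seconds; required downstream for 4D series.
#' @param units Free-text unit label.
#'
#' @return An object of class `brain_vol`.
#' @export
brain_vol <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                      tr = NULL, units = "") {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) {
    abort("`data` must be a 3D or 4D array.")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive mm values.")
  }
  if (is.null(affine)) {
    affine <- default_affine(dim(data)[1:3], voxel_size)
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) abort("`affine` must be 4x4.")
  structure(
    list(data = data, voxel_size = voxel_size, affine = affine,
         tr = tr, units = units),
    class = "brain_vol"
  )
}

default_affine <- function(grid_shape, voxel_size) {
  centre <- -voxel_size * (grid_shape - 1) / 2
  rbind(cbind(diag(voxel_size), centre), c(0, 0, 0, 1))
}

#' @export
print.brain_vol <- function(x, ...) {
  dims <- paste(dim(x$data), collapse = " x ")
  cat("<brain_vol> ", dims, " voxels, ",
      paste(signif(x$voxel_size, 3), collapse = " x "), " mm",
      if (!is.null(x$tr)) paste0(", TR = ", x$tr, " s"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.brain_vol <- function(x) dim(x$data)

is_brain_vol <- function(x) inherits(x, "brain_vol")

#' Coerce to a plain data array
#'
#' @param x A `brain_vol` or array.
#' @return The underlying numeric array.
#' @export
vol_data <- function(x) {
  if (is_brain_vol(x)) x$data else as.array(x)
}

# Accept a brain_vol, logical array, or 0/1 numeric array as a mask and
# return a logical array checked against a companion grid shape.
as_mask <- function(mask, grid_shape = NULL) {
  m <- vol_data(mask)
  m <- array(as.logical(m != 0 & !is.na(m)), dim = dim(m))
  if (!is.null(grid_shape) && !identical(dim(m), as.integer(grid_shape))) {
    abort("Mask shape does not match the companion image.")
  }
  if (!any(m)) abort("Mask is empty.")
  m
}

#' Convert between voxel indices and world coordinates
#'
#' `vox_to_mm()` maps 0-based voxel indices (rows of an `n x 3` matrix)
#' to world mm through a 4x4 affine; `mm_to_vox()` is its inverse
#' (returning fractional 0-based indices).
#'
#' @param affine 4x4 voxel-to-world transform.
#' @param ijk `n x 3` matrix (or length-3 vector) of 0-based voxel
#'   indices.
#' @return `n x 3` numeric matrix.
#' @export
vox_to_mm <- function(affine, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3)
  ijk <- rbind(t(as.matrix(ijk)), 1)
  t(affine %*% ijk)[, 1:3, drop = FALSE]
}

#' @rdname vox_to_mm
#' @param xyz `n x 3` matrix (or length-3 vector) of world coordinates in
#'   mm.
#' @export
mm_to_vox <- function(affine, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  xyz <- rbind(t(as.matrix(xyz)), 1)
  t(solve(affine) %*% xyz)[, 1:3, drop = FALSE]
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param tr Repetition time in seconds for 4D series; when `NULL` the
#'   value stored in the header's fourth pixdim slot is used if positive.
#' @return A [brain_vol].
#' @export
read_volume <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  data <- array(as.numeric(img), dim = dim(img))
  if (is.null(tr) && length(dim(data)) == 4L && length(pd) >= 4 && pd[4] > 0) {
    tr <- pd[4]
  }
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  brain_vol(data, voxel_size = abs(pd[1:3]), affine = affine, tr = tr)
}

#' Write a NIfTI-1 volume
#'
#' @param vol A [brain_vol] (or plain array, written with unit voxels).
#' @param path Output path; `.nii.gz` compresses.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!is_brain_vol(vol)) vol <- brain_vol(vol)
  img <- RNifti::asNifti(vol$data)
  nd <- length(dim(vol$data))
  pd <- c(vol$voxel_size, if (is.null(vol$tr)) 1 else vol$tr)
  RNifti::pixdim(img) <- pd[seq_len(nd)]
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
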