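#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per voxel, the BOLD series is (optionally) linearly detrended, Fourier
#' transformed, and converted to a single-sided amplitude spectrum
#' `a_f = 2 |X_f| / T`; ALFF is the mean of `a_f` over the DFT bins whose
#' frequency lies in `[low, high]` (closed interval). The amplitude scale
#' is pinned by this convention; group contrasts are invariant to it.
#'
#' @param series 4D [brain_vol] with a repetition time (`tr`, seconds).
#' @param mask Brain mask (logical array or volume); voxels outside are 0.
#' @param band Frequency band `c(low, high)` in Hz with
#'   `0 < low < high < 1/(2 tr)`.
#' @param detrend Remove a per-voxel linear trend (with intercept) before
#'   the transform. The exact sinusoid-amplitude identity `ALFF = A/K`
#'   holds only with `detrend = FALSE`; detrending perturbs bin amplitudes
#'   by a small broadband leakage term.
#' @param standardize `"none"` (default) or `"mean"` to divide the map by
#'   its within-mask mean (mALFF).
#' @return 3D [brain_vol] of ALFF values.
#' @export
compute_alff <- function(series, mask, band = c(0.01, 0.10),
                         detrend = TRUE,
                         standardize = c("none", "mean")) {
  standardize <- match.arg(standardize)
  if (!is_brain_vol(series) || length(dim(series$data)) != 4L) {
    abort("`series` must be a 4D brain_vol.")
  }
  tr <- series$tr
  if (is.null(tr) || !is.finite(tr) || tr <= 0) {
    abort("`series` needs a positive repetition time (tr).")
  }
  nt <- dim(series$data)[4]
  if (nt < 32L) abort("Need at least 32 time points for a usable spectrum.")
  band <- as.numeric(band)
  nyq <- 1 / (2 * tr)
  if (length(band) != 2L || !(0 < band[1] && band[1] < band[2] &&
                              band[2] < nyq + 1e-12)) {
    abort(sprintf("Band must satisfy 0 < low < high < Nyquist (%.4g Hz).", nyq))
  }
  m <- as_mask(mask, dim(series$data)[1:3])

  freqs <- seq_len(floor(nt / 2)) / (nt * tr)
  in_band <- freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12
  if (!any(in_band)) {
    abort(sprintf(
      "No DFT bins fall in [%.4g, %.4g] Hz; need at least T = %d time points at tr = %g s.",
      band[1], band[2], ceiling(1 / (tr * (band[2] - band[1]))), tr))
  }
  bins <- which(in_band) + 1L  # +1: fft index 1 is the DC term

  ts_mat <- matrix(aperm(series$data, c(4, 1, 2, 3)), nrow = nt)[, m, drop = FALSE]
  if (detrend) {
    x <- cbind(1, seq_len(nt))
    ts_mat <- ts_mat - x %*% solve(crossprod(x), crossprod(x, ts_mat))
  }
  amp <- 2 * Mod(stats::mvfft(ts_mat)[bins, , drop = FALSE]) / nt
  alff_vals <- colMeans(amp)

  out <- array(0, dim = dim(series$data)[1:3])
  out[m] <- alff_vals
  if (standardize == "mean") {
    mu <- mean(alff_vals)
    if (mu <= 0) abort("Cannot standardize: within-mask mean ALFF is not positive.")
    out[m] <- alff_vals / mu
  }
  brain_vol(out, voxel_size = series$voxel_size, affine = series$affine,
            units = "amplitude")
}

#' Z-score a volume within a mask
#'
#' Subtracts the within-mask mean and divides by the within-mask standard
#' deviation (population convention, dividing by N). Out-of-mask voxels
#' are set to 0.
#'
#' @param vol 3D [brain_vol] or array.
#' @param mask Brain mask.
#' @return 3D [brain_vol] of z values.
#' @export
zscore_volume <- function(vol, mask) {
  if (!is_brain_vol(vol)) vol <- brain_vol(vol)
  m <- as_mask(mask, dim(vol$data))
  v <- vol$data[m]
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (!is.finite(sdev) || sdev == 0) {
    abort("Degenerate input: volume is constant within the mask.")
  }
  out <- array(0, dim = dim(vol$data))
  out[m] <- (v - mu) / sdev
  brain_vol(out, voxel_size = vol$voxel_size, affine = vol$affine,
            units = "z")
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian convolution with per-axis
#' `sigma = fwhm / (voxel_size * 2 sqrt(2 log 2))`, zero-padded at the grid
#' boundary. When a mask is supplied it is applied after smoothing.
#'
#' @param vol 3D [brain_vol] or array.
#' @param fwhm_mm Kernel full width at half maximum in mm (scalar or per
#'   axis); 0 is the identity.
#' @param mask Optional mask applied after smoothing.
#' @return Smoothed 3D [brain_vol].
#' @export
gaussian_smooth <- function(vol, fwhm_mm, mask = NULL) {
  if (!is_brain_vol(vol)) vol <- brain_vol(vol)
  fwhm_mm <- as.numeric(fwhm_mm)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  if (length(fwhm_mm) != 3L || any(fwhm_mm < 0)) {
    abort("`fwhm_mm` must be non-negative (scalar or length 3).")
  }
  sigma_vox <- fwhm_mm / (vol$voxel_size * (2 * sqrt(2 * log(2))))
  out <- vol$data
  for (axis in 1:3) {
    if (sigma_vox[axis] <= 0) next
    out <- convolve_axis(out, gaussian_kernel(sigma_vox[axis]), axis)
  }
  if (!is.null(mask)) out[!as_mask(mask, dim(out))] <- 0
  brain_vol(out, voxel_size = vol$voxel_size, affine = vol$affine,
            units = vol$units)
}

gaussian_kernel <- function(sigma, radius = max(1L, ceiling(6 * sigma))) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution of a 3D array along `axis` with zero padding, via a dense
# banded convolution matrix (fast for the grid sizes used here).
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  cm <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    cm[cbind(i[ok], j[ok])] <- kernel[o + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  x <- cm %*% matrix(x, nrow = n)
  aperm(array(x, dim = d[perm]), order(perm))
}
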