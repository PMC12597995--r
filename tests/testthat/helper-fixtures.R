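# Small in-code fixtures shared across tests.

full_mask <- function(shape) array(TRUE, dim = shape)

# A 4D series holding the same time course at every voxel.
uniform_series <- function(signal, shape = c(4, 4, 3), tr = 2) {
  nt <- length(signal)
  arr <- array(rep(signal, each = prod(shape)), dim = c(shape, nt))
  brain_vol(arr, tr = tr)
}

# Closed interval count of DFT bins of a length-nt series inside a band.
n_band_bins <- function(nt, tr, band = c(0.01, 0.10)) {
  freqs <- seq_len(floor(nt / 2)) / (nt * tr)
  sum(freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12)
}

# Naive O(T^2) single-sided amplitude spectrum: the DFT by direct
# summation, independent of the fft-based implementation.
naive_amplitude_spectrum <- function(x) {
  nt <- length(x)
  ks <- seq_len(floor(nt / 2))
  vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(nt - 1)) / nt))
    im <- sum(x * sin(-2 * pi * k * (0:(nt - 1)) / nt))
    2 * sqrt(re^2 + im^2) / nt
  }, numeric(1))
}

# Per-donor matrices with identical gene sets for filter/combine tests.
toy_donor_matrices <- function(n_donors = 3, n_regions = 12, n_genes = 6,
                               seed = 1, noise_sd = 0, missing = list()) {
  set.seed(seed)
  base <- matrix(rnorm(n_regions * n_genes), n_regions, n_genes)
  lapply(seq_len(n_donors), function(d) {
    vals <- base + matrix(rnorm(n_regions * n_genes, sd = noise_sd),
                          n_regions, n_genes)
    if (length(missing) >= d && length(missing[[d]])) {
      vals[missing[[d]], ] <- NA_real_
    }
    region_gene_matrix(seq_len(n_regions), sprintf("G%03d", seq_len(n_genes)),
                       vals)
  })
}

# All permutations of 1..n (n small), for exhaustive permutation nulls.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}
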