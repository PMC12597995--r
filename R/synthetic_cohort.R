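# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Imaging cohort specification
#'
#' Parameters of the synthetic two-group imaging cohort. Defaults emulate
#' the study regime this pipeline was built for: 34 patients vs 32
#' controls, a 0.01-0.10 Hz band of interest, young-adult demographics
#' (age mean 23, SD 6.5, truncated to 14-59; female-majority sex ratio),
#' and head-motion summaries with a higher patient mean.
#'
#' @param n_per_group Subjects per arm; scalar or `c(patients, controls)`.
#' @param grid_shape Voxels per axis (length 3).
#' @param voxel_size mm per axis.
#' @param tr Repetition time, seconds (4D cohorts).
#' @param n_timepoints Time points per 4D series.
#' @param effect_regions Integer region IDs carrying the group effect.
#' @param effect_size Injected group difference in units of `noise_sd`
#'   (for 3D perfusion maps this is the voxel-level Cohen's d; for 4D it
#'   is the amplitude difference of the injected oscillation).
#' @param band `c(low, high)` Hz of the injected oscillation.
#' @param noise_sd Additive noise SD, arbitrary units.
#' @param baseline Baseline map value (3D) or oscillation amplitude shared
#'   by both groups (4D).
#' @param seed Integer; fully determines the cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(34, 32), grid_shape = c(20, 20, 14),
                        voxel_size = 3, tr = 2, n_timepoints = 200,
                        effect_regions = integer(), effect_size = 1.5,
                        band = c(0.01, 0.10), noise_sd = 1,
                        baseline = 0, seed = 1L) {
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 2L),
            noise_sd >= 0, is.finite(effect_size))
  nyq <- 1 / (2 * tr)
  if (!(0 < band[1] && band[1] < band[2] && band[2] < nyq)) {
    abort(sprintf("Band must lie strictly inside (0, Nyquist = %.4g Hz).", nyq))
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, tr = tr,
                 n_timepoints = as.integer(n_timepoints),
                 effect_regions = as.integer(effect_regions),
                 effect_size = effect_size, band = as.numeric(band),
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

check_cohort_atlas <- function(spec, atlas) {
  if (!identical(dim(atlas$labels$data), spec$grid_shape)) {
    abort("Atlas grid does not match spec$grid_shape.")
  }
  if (!all(spec$effect_regions %in% atlas$regions$region_id)) {
    abort("effect_regions must be a subset of the atlas region IDs.")
  }
}

synth_covariates <- function(spec) {
  n <- spec$n_per_group
  group <- rep(c("MDD", "HC"), n)
  n_all <- sum(n)
  age <- rnorm_trunc(n_all, 23.0, 6.5, 14, 59)
  sex <- ifelse(runif(n_all) < 52 / 66, "F", "M")
  fd_mean <- ifelse(group == "MDD", 0.62, 0.51)
  fd_sd <- ifelse(group == "MDD", 0.31, 0.16)
  mean_fd <- rnorm_trunc(n_all, fd_mean, fd_sd, lower = 0.01)
  tibble(subject_id = sprintf("sub-%03d", seq_len(n_all)),
         group = group, age = age, sex = sex, mean_fd = mean_fd)
}

#' Generate a 4D BOLD-like cohort
#'
#' Every voxel receives Gaussian noise; voxels inside `effect_regions`
#' additionally carry a sinusoid at the band-interior DFT frequency
#' nearest the band centre, with amplitude `baseline` in controls and
#' `baseline + effect_size * noise_sd` in patients, so the injected ALFF
#' difference has the closed form `effect_size * noise_sd / K` for `K`
#' band bins.
#'
#' @param spec A [cohort_spec()].
#' @param atlas A [parcellation_atlas] on `spec$grid_shape`.
#' @return List with `volumes` (4D [brain_vol]s), `covariates` (tibble),
#'   `mask`, and `truth` (injected frequency, amplitudes, expected
#'   regional ALFF difference).
#' @export
generate_bold_cohort <- function(spec, atlas) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_cohort_atlas(spec, atlas)
  nt <- spec$n_timepoints
  freqs <- seq_len(floor(nt / 2)) / (nt * spec$tr)
  in_band <- which(freqs >= spec$band[1] - 1e-12 & freqs <= spec$band[2] + 1e-12)
  if (!length(in_band)) abort("No DFT bin inside the band; increase n_timepoints.")
  kbin <- in_band[which.min(abs(freqs[in_band] - mean(spec$band)))]
  f_sig <- freqs[kbin]
  k_band <- length(in_band)

  lab <- vol_data(atlas$labels)
  effect_vox <- which(lab %in% spec$effect_regions)
  mask <- lab > 0L
  tt <- (seq_len(nt) - 1L) * spec$tr

  with_seed(spec$seed, {
    covars <- synth_covariates(spec)
    amp_delta <- spec$effect_size * spec$noise_sd
    vols <- lapply(seq_len(nrow(covars)), function(i) {
      amp <- spec$baseline + if (covars$group[i] == "MDD") amp_delta else 0
      arr <- array(rnorm(prod(spec$grid_shape) * nt, sd = spec$noise_sd),
                   dim = c(spec$grid_shape, nt))
      if (length(effect_vox) && amp != 0) {
        phase <- runif(1, 0, 2 * pi)
        sig <- amp * sin(2 * pi * f_sig * tt + phase)
        nv <- prod(spec$grid_shape)
        for (t in seq_len(nt)) {
          arr[effect_vox + (t - 1L) * nv] <- arr[effect_vox + (t - 1L) * nv] + sig[t]
        }
      }
      brain_vol(arr, voxel_size = atlas$labels$voxel_size,
                affine = atlas$labels$affine, tr = spec$tr)
    })
    truth <- list(
      modality = "bold",
      signal_freq_hz = f_sig, n_band_bins = k_band,
      amplitude_patient = spec$baseline + amp_delta,
      amplitude_control = spec$baseline,
      effect_regions = spec$effect_regions,
      expected_alff_difference = amp_delta / k_band,
      covariate_model = list(age = c(23, 6.5), female_rate = 52 / 66,
                             fd_mdd = c(0.62, 0.31), fd_hc = c(0.51, 0.16)),
      seed = spec$seed
    )
    list(volumes = vols, covariates = covars,
         mask = brain_vol(mask * 1, voxel_size = atlas$labels$voxel_size,
                          affine = atlas$labels$affine),
         truth = truth)
  })
}

#' Generate a 3D perfusion-like cohort
#'
#' Perfusion maps are `baseline + noise`, with an additive regional shift
#' of `effect_size * noise_sd` in patients inside `effect_regions` — a
#' voxel-level Cohen's d of `effect_size`.
#'
#' @inheritParams generate_bold_cohort
#' @return List with `volumes` (3D [brain_vol]s), `covariates`, `mask`,
#'   `truth`.
#' @export
generate_cbf_cohort <- function(spec, atlas) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_cohort_atlas(spec, atlas)
  lab <- vol_data(atlas$labels)
  effect_vox <- which(lab %in% spec$effect_regions)
  mask <- lab > 0L

  with_seed(spec$seed, {
    covars <- synth_covariates(spec)
    shift <- spec$effect_size * spec$noise_sd
    vols <- lapply(seq_len(nrow(covars)), function(i) {
      arr <- spec$baseline +
        array(rnorm(prod(spec$grid_shape), sd = spec$noise_sd),
              dim = spec$grid_shape)
      if (covars$group[i] == "MDD" && length(effect_vox)) {
        arr[effect_vox] <- arr[effect_vox] + shift
      }
      brain_vol(arr, voxel_size = atlas$labels$voxel_size,
                affine = atlas$labels$affine, units = "ml/100g/min")
    })
    truth <- list(
      modality = "cbf",
      effect_regions = spec$effect_regions,
      expected_shift = shift, cohens_d = spec$effect_size,
      covariate_model = list(age = c(23, 6.5), female_rate = 52 / 66,
                             fd_mdd = c(0.62, 0.31), fd_hc = c(0.51, 0.16)),
      seed = spec$seed
    )
    list(volumes = vols, covariates = covars,
         mask = brain_vol(mask * 1, voxel_size = atlas$labels$voxel_size,
                          affine = atlas$labels$affine),
         truth = truth)
  })
}

#' Donor expression specification
#'
#' Defaults emulate a multi-donor postmortem expression resource at desk
#' scale: six donors, donor-specific unsampled regions, and a planted
#' spatial component carried by a fraction of the genes.
#'
#' @param n_regions,n_genes,n_donors Matrix dimensions and donor count.
#' @param latent_map Numeric length `n_regions` (or a [regional_vector]):
#'   the spatial pattern the loading genes track.
#' @param loading_fraction Fraction of genes loading on the latent map.
#' @param loading_sd SD of the loading magnitudes around 1 (signs random).
#' @param noise_sd Donor-level expression noise SD.
#' @param missing_rate Per-donor probability that a region is unsampled.
#' @param background_sd SD of a donor-shared spatial profile given to
#'   non-loading genes. The default 0 makes non-loading genes pure donor
#'   noise (so the stability filter retains about the null false-positive
#'   fraction of them); a positive value emulates the donor-stable but
#'   phenotype-unrelated expression structure of real atlases, so most
#'   genes survive the filter into the tested universe.
#' @param background_factors Number of shared spatial components the
#'   background profiles mix (real regional expression is dominated by a
#'   few spatial components, so the background is low-rank rather than
#'   gene-wise independent).
#' @param seed Integer seed.
#' @return An `expression_spec` list.
#' @export
expression_spec <- function(n_regions, n_genes, n_donors = 6,
                            latent_map = NULL, loading_fraction = 0.1,
                            loading_sd = 0.25, noise_sd = 0.5,
                            missing_rate = 0.1, background_sd = 0,
                            background_factors = 5L, seed = 1L) {
  stopifnot(n_regions >= 3, n_genes >= 1, n_donors >= 1,
            loading_fraction >= 0, loading_fraction <= 1,
            missing_rate >= 0, missing_rate < 1, noise_sd >= 0)
  if (is.data.frame(latent_map)) latent_map <- latent_map$value
  if (is.null(latent_map)) {
    latent_map <- with_seed(seed + 1L, rnorm(n_regions))
  }
  if (length(latent_map) != n_regions) {
    abort("latent_map length must equal n_regions.")
  }
  structure(list(n_regions = as.integer(n_regions),
                 n_genes = as.integer(n_genes),
                 n_donors = as.integer(n_donors),
                 latent_map = as.numeric(latent_map),
                 loading_fraction = loading_fraction,
                 loading_sd = loading_sd, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 background_sd = background_sd,
                 background_factors = as.integer(background_factors),
                 seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate multi-donor expression data
#'
#' Loading genes express `loading * latent_map + noise`; the rest are
#' pure noise (plus a donor-shared spatial profile when `background_sd`
#' is positive). Each donor leaves out about `missing_rate` of the regions
#' (absent rows, not zeros). With an atlas, each sampled region also gets
#' MNI-coordinate samples at labelled voxel centres so the sample-to-region
#' assignment step can be exercised end to end.
#'
#' @param spec An [expression_spec()].
#' @param atlas Optional [parcellation_atlas] whose first
#'   `spec$n_regions` regions anchor the sample coordinates.
#' @return List with `donors` (per-donor [region_gene_matrix] in
#'   `$matrix`, and `$samples` coordinates when an atlas is given) and
#'   `truth` (loading gene IDs, loadings, latent map).
#' @export
generate_donor_expression <- function(spec, atlas = NULL) {
  stopifnot(inherits(spec, "expression_spec"))
  gene_ids <- sprintf("G%05d", seq_len(spec$n_genes))
  region_ids <- seq_len(spec$n_regions)
  if (!is.null(atlas)) {
    if (nrow(atlas$regions) < spec$n_regions) {
      abort("Atlas has fewer regions than spec$n_regions.")
    }
    region_ids <- atlas$regions$region_id[seq_len(spec$n_regions)]
    rvi <- region_voxel_index(atlas)
  }
  with_seed(spec$seed, {
    n_load <- round(spec$loading_fraction * spec$n_genes)
    loading_idx <- sort(sample.int(spec$n_genes, n_load))
    loadings <- numeric(spec$n_genes)
    if (n_load > 0) {
      loadings[loading_idx] <- sample(c(-1, 1), n_load, replace = TRUE) *
        rnorm_trunc(n_load, 1, spec$loading_sd, lower = 0.1)
    }
    signal <- outer(spec$latent_map, loadings)  # regions x genes
    if (spec$background_sd > 0) {
      nf <- max(1L, spec$background_factors)
      factors <- matrix(rnorm(spec$n_regions * nf), spec$n_regions, nf)
      coef <- matrix(rnorm(nf * spec$n_genes, sd = spec$background_sd /
                             sqrt(nf)), nf, spec$n_genes)
      bg <- factors %*% coef
      bg[, loading_idx] <- 0
      signal <- signal + bg
    }
    donors <- lapply(seq_len(spec$n_donors), function(d) {
      vals <- signal +
        matrix(rnorm(spec$n_regions * spec$n_genes, sd = spec$noise_sd),
               spec$n_regions, spec$n_genes)
      missing <- runif(spec$n_regions) < spec$missing_rate
      vals[missing, ] <- NA_real_
      mat <- region_gene_matrix(region_ids, gene_ids, vals)
      out <- list(donor_id = sprintf("donor-%02d", d), matrix = mat)
      if (!is.null(atlas)) {
        present <- which(!missing)
        vox <- vapply(present, function(ri) {
          vv <- rvi[[as.character(region_ids[ri])]]
          vv[sample.int(length(vv), 1L)]
        }, integer(1))
        ijk <- arrayInd(vox, dim(atlas$labels$data)) - 1L
        mm <- vox_to_mm(atlas$labels$affine, ijk)
        out$samples <- donor_expression(
          donor_id = out$donor_id,
          coords = mm,
          expr = vals[present, , drop = FALSE],
          gene_ids = gene_ids
        )
      }
      out
    })
    truth <- list(
      gene_ids = gene_ids,
      loading_genes = gene_ids[loading_idx],
      loadings = setNames(loadings, gene_ids),
      latent_map = regional_vector(region_ids, spec$latent_map),
      seed = spec$seed
    )
    list(donors = donors, truth = truth)
  })
}

#' Generate a synthetic annotation collection
#'
#' Draws `n_terms` gene-set terms over the supplied universe. Planted
#' terms draw at least `planted_purity` of their members from the loading
#' genes recorded in `truth`; the rest sample uniformly. Categories cycle
#' over BP, CC, MF, PATHWAY.
#'
#' @param genes Character universe of gene IDs.
#' @param truth Truth object from [generate_donor_expression()] (used for
#'   its `loading_genes`), or `NULL` for no planted enrichment.
#' @param n_terms Number of terms.
#' @param term_size_range `c(min, max)` members per term.
#' @param n_planted Number of planted-enriched terms.
#' @param planted_purity Minimum fraction of planted-term members drawn
#'   from the loading genes.
#' @param seed Integer seed.
#' @return List with `collection` (annotation tibble: `term_id`, `name`,
#'   `category`, `genes` list-column) and `planted_terms` (IDs).
#' @export
generate_annotation <- function(genes, truth = NULL, n_terms = 50,
                                term_size_range = c(10, 60),
                                n_planted = if (is.null(truth)) 0L else 3L,
                                planted_purity = 0.75, seed = 1L) {
  stopifnot(length(genes) > 0, n_terms >= 1,
            term_size_range[1] >= 1,
            term_size_range[2] >= term_size_range[1])
  if (term_size_range[2] > length(genes)) {
    abort("term_size_range exceeds the number of genes.")
  }
  loading <- if (is.null(truth)) character() else
    intersect(truth$loading_genes, genes)
  if (n_planted > 0 && !length(loading)) {
    abort("Planted terms requested but truth has no loading genes in the universe.")
  }
  cats <- c("BP", "CC", "MF", "PATHWAY")
  with_seed(seed, {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms,
                    replace = TRUE)
    planted_ids <- character()
    terms <- lapply(seq_len(n_terms), function(i) {
      sz <- sizes[i]
      if (i <= n_planted) {
        n_from <- min(length(loading), ceiling(planted_purity * sz))
        members <- c(sample(loading, n_from),
                     sample(setdiff(genes, loading), sz - n_from))
      } else {
        members <- sample(genes, sz)
      }
      tibble(term_id = sprintf("T%04d", i),
             name = sprintf("synthetic term %d", i),
             category = cats[(i - 1L) %% 4L + 1L],
             genes = list(sort(unique(members))))
    })
    collection <- dplyr::bind_rows(terms)
    list(collection = collection,
         planted_terms = collection$term_id[seq_len(n_planted)])
  })
}
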