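#' Generate a synthetic study on disk and run the full pipeline
#'
#' Builds a complete desk-scale study — block atlas, 4D BOLD cohort with
#' a band-limited amplitude effect, 3D perfusion cohort with a regional
#' shift, donor expression tables whose planted spatial component tracks
#' the effect map, and GMT annotations enriched for the loading genes —
#' writes everything to `out_dir` in the pipeline's file formats, runs
#' [run_pipeline()] on it, and scores recovery against the generator
#' truth.
#'
#' @param out_dir Output directory (created).
#' @param seed Integer; determines the whole demo.
#' @param n_per_group Subjects per arm.
#' @param grid_shape,n_regions,voxel_size Atlas geometry.
#' @param effect_regions Planted region IDs (default: 3 regions).
#' @param effect_size Planted effect size (noise-SD units).
#' @param n_timepoints,tr BOLD series length and repetition time.
#' @param n_genes,n_donors,loading_fraction,expr_noise_sd,background_sd,missing_rate
#'   Expression generator settings; the positive `background_sd` gives
#'   non-loading genes donor-stable spatial structure so the
#'   stability-filtered gene universe stays much larger than the
#'   selected sets, as in real expression atlases.
#' @param n_perm,n_boot,alpha Inference settings (demo-scale defaults).
#' @param fwhm Smoothing kernel FWHM in mm.
#' @return List with the pipeline `manifest`, `truth`, and recovery
#'   tibbles `region_recovery` (per modality) and `gene_recovery`.
#' @export
run_demo <- function(out_dir, seed = 1L,
                     n_per_group = c(16, 16),
                     grid_shape = c(16, 16, 12), n_regions = 36,
                     voxel_size = 3, effect_regions = c(5L, 16L, 27L),
                     effect_size = 1.5, n_timepoints = 120, tr = 2,
                     n_genes = 200, n_donors = 6, loading_fraction = 0.15,
                     expr_noise_sd = 0.4, background_sd = 0.5,
                     missing_rate = 0.1,
                     n_perm = 999, n_boot = 500, alpha = 0.05,
                     fwhm = 6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data_dir <- file.path(out_dir, "data")
  dir.create(data_dir, showWarnings = FALSE)
  atlas <- synthetic_atlas(grid_shape, n_regions, voxel_size)
  write_volume(atlas$labels, file.path(data_dir, "atlas.nii.gz"))
  write_region_table(atlas, file.path(data_dir, "regions.tsv"))

  spec_common <- list(n_per_group = n_per_group, grid_shape = grid_shape,
                      voxel_size = voxel_size, tr = tr,
                      n_timepoints = n_timepoints,
                      effect_regions = effect_regions,
                      effect_size = effect_size)
  bold <- generate_bold_cohort(
    do.call(cohort_spec, c(spec_common, list(baseline = 1, seed = seed))),
    atlas)
  cbf <- generate_cbf_cohort(
    do.call(cohort_spec, c(spec_common, list(baseline = 50,
                                             seed = seed + 1L))),
    atlas)
  manifests <- list()
  for (mn in c("bold", "cbf")) {
    cohort <- if (mn == "bold") bold else cbf
    paths <- vapply(seq_along(cohort$volumes), function(i) {
      p <- file.path(data_dir, sprintf("%s_%s.nii.gz", mn,
                                       cohort$covariates$subject_id[i]))
      write_volume(cohort$volumes[[i]], p)
      p
    }, character(1))
    man <- dplyr::mutate(cohort$covariates, path = paths)
    mp <- file.path(data_dir, paste0(mn, "_manifest.tsv"))
    readr::write_tsv(man, mp)
    manifests[[mn]] <- mp
  }

  # Latent expression pattern tracking the planted effect support, with
  # spatial jitter so loading genes are correlated with - not equal to -
  # the imaging effect map.
  latent <- with_seed(seed + 2L, {
    ind <- as.numeric(atlas$regions$region_id %in% effect_regions)
    2 * ind + rnorm(n_regions, sd = 0.3)
  })
  expr <- generate_donor_expression(
    expression_spec(n_regions = n_regions, n_genes = n_genes,
                    n_donors = n_donors, latent_map = latent,
                    loading_fraction = loading_fraction,
                    noise_sd = expr_noise_sd, background_sd = background_sd,
                    missing_rate = missing_rate, seed = seed + 3L),
    atlas)
  donor_paths <- vapply(expr$donors, function(d) {
    p <- file.path(data_dir, paste0(d$donor_id, ".tsv"))
    write_donor_table(d$samples, p)
    p
  }, character(1))

  annot <- generate_annotation(expr$truth$gene_ids, expr$truth,
                               n_terms = 40, term_size_range = c(8, 40),
                               seed = seed + 4L)
  gmt_paths <- list()
  for (cat in unique(annot$collection$category)) {
    p <- file.path(data_dir, paste0("annot_", tolower(cat), ".gmt"))
    write_gmt(dplyr::filter(annot$collection, .data$category == cat), p)
    gmt_paths[[cat]] <- p
  }

  config <- modifyList(default_config(), list(
    output_dir = file.path(out_dir, "results"),
    seed = seed,
    atlas_labels = file.path(data_dir, "atlas.nii.gz"),
    atlas_regions = file.path(data_dir, "regions.tsv"),
    modalities = list(
      alff = list(manifest = manifests$bold, kind = "bold", tr = tr),
      cbf = list(manifest = manifests$cbf, kind = "cbf")),
    donors = as.list(donor_paths),
    gmt = gmt_paths,
    fwhm = fwhm, n_perm = n_perm, n_boot = n_boot, alpha = alpha))
  yaml::write_yaml(config[setdiff(names(config), "modalities")],
                   file.path(out_dir, "config.yaml"))
  manifest <- run_pipeline(config)

  region_recovery <- dplyr::bind_rows(lapply(c("alff", "cbf"), function(mn) {
    dplyr::mutate(
      score_region_recovery(manifest$clusters[[mn]], atlas, effect_regions),
      modality = mn, .before = 1)
  }))
  gene_recovery <- dplyr::bind_rows(lapply(c("alff", "cbf"), function(mn) {
    sel <- manifest$pls_results[[mn]]$selected
    dplyr::mutate(
      score_gene_recovery(sel, expr$truth,
                          universe = manifest$pls_results[[mn]]$gene_ids),
      modality = mn, .before = 1)
  }))
  list(manifest = manifest,
       truth = list(imaging = bold$truth, cbf = cbf$truth,
                    expression = expr$truth,
                    planted_terms = annot$planted_terms),
       region_recovery = region_recovery,
       gene_recovery = gene_recovery,
       config = config)
}
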