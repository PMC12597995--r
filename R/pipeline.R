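default_config <- function() {
  list(band = c(0.01, 0.10), fwhm = 8, voxel_p = 0.001, cluster_p = 0.05,
       stability_threshold = 0.1, normalization = "robust_sigmoid",
       tolerance_mm = 2, n_perm = 10000, n_boot = 5000, alpha = 0.05,
       min_overlap = 2)
}

#' Validate a pipeline configuration
#'
#' Returns findings (not errors): missing files, band/Nyquist conflicts,
#' missing seed, out-of-range thresholds. An empty tibble means the
#' configuration is runnable.
#'
#' @param config Named list (or path to a YAML file).
#' @return Tibble with columns `level` (`"error"`/`"warning"`) and
#'   `message`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(default_config(), config)
  findings <- list()
  note <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- tibble(level = level, message = msg)
  }
  if (is.null(config$seed)) note("error", "No seed in config.")
  for (key in c("atlas_labels", "atlas_regions")) {
    if (is.null(config[[key]])) {
      note("error", paste0("Missing path: ", key))
    } else if (!file.exists(config[[key]])) {
      note("error", paste0("File not found: ", config[[key]]))
    }
  }
  if (is.null(config$modalities) || !length(config$modalities)) {
    note("error", "No modalities configured.")
  } else {
    for (mn in names(config$modalities)) {
      mod <- config$modalities[[mn]]
      if (is.null(mod$manifest) || !file.exists(mod$manifest)) {
        note("error", paste0("Manifest missing for modality ", mn))
      }
      if (identical(mod$kind, "bold")) {
        tr <- mod$tr
        if (is.null(tr)) {
          note("error", paste0("BOLD modality ", mn, " needs a tr."))
        } else if (config$band[2] >= 1 / (2 * tr)) {
          note("error", sprintf(
            "Band high %.3g Hz is not below Nyquist %.3g Hz for modality %s.",
            config$band[2], 1 / (2 * tr), mn))
        }
      }
    }
  }
  if (is.null(config$donors) || !length(config$donors)) {
    note("error", "No donor tables configured.")
  } else {
    for (p in config$donors) {
      if (!file.exists(p)) note("error", paste0("File not found: ", p))
    }
  }
  if (!is.null(config$gmt)) {
    for (p in unlist(config$gmt)) {
      if (!file.exists(p)) note("error", paste0("File not found: ", p))
    }
  }
  if (!(config$alpha > 0 && config$alpha < 1)) {
    note("error", "alpha must be in (0, 1).")
  }
  if (length(findings)) dplyr::bind_rows(findings) else
    tibble(level = character(), message = character())
}

read_manifest <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "group", "age", "sex", "mean_fd", "path")
  if (!all(need %in% names(tab))) {
    abort(paste0("Manifest needs columns: ", paste(need, collapse = ", ")))
  }
  tab
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the end-to-end imaging-transcriptomics pipeline
#'
#' Executes, per modality: metric maps (ALFF for 4D BOLD, z-scored CBF
#' for 3D perfusion), Gaussian smoothing, the covariate-adjusted group
#' GLM with GRF cluster correction, and regional summarization of the t
#' map; then the donor expression matrix (assignment, stability filter,
#' averaging), PLS1 with permutation and bootstrap inference per
#' modality, gene-set selection and overlap, and over-representation
#' analysis of each set. Every table is written under
#' `config$output_dir` together with a run manifest (parameters, seeds,
#' parameter hash, output paths).
#'
#' @param config Named list or path to a YAML file. Required keys:
#'   `output_dir`, `seed`, `atlas_labels`, `atlas_regions`, `modalities`
#'   (named list with `manifest`, `kind` = `"bold"`/`"cbf"`, and `tr` for
#'   BOLD), `donors` (paths). Optional keys default to the study
#'   settings: `band` 0.01-0.10 Hz, `fwhm` 8 mm, `voxel_p` 0.001,
#'   `cluster_p` 0.05, `stability_threshold` 0.1, `n_perm` 10000,
#'   `n_boot` 5000, `alpha` 0.05, `gmt` (named category = path list),
#'   `min_overlap` 2.
#' @return The run manifest (named list), invisibly; also written as
#'   `run_manifest.yaml`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(default_config(), config)
  findings <- validate_config(config)
  errs <- findings$message[findings$level == "error"]
  if (length(errs)) {
    abort(paste0("Invalid config:\n", paste("-", errs, collapse = "\n")))
  }
  out_dir <- config$output_dir
  if (is.null(out_dir)) abort("config$output_dir is required.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  register <- function(name, path) outputs[[name]] <<- path

  atlas <- run_stage("atlas", {
    parcellation_atlas(
      read_volume(config$atlas_labels),
      readr::read_tsv(config$atlas_regions, show_col_types = FALSE,
                      progress = FALSE))
  })
  mask <- if (!is.null(config$mask)) read_volume(config$mask) else
    brain_vol((vol_data(atlas$labels) > 0) * 1,
              voxel_size = atlas$labels$voxel_size,
              affine = atlas$labels$affine)

  expr_build <- run_stage("expression_atlas", {
    donors <- lapply(config$donors, read_donor_table)
    build_expression_matrix(
      donors, atlas,
      stability_threshold = config$stability_threshold,
      tolerance_mm = config$tolerance_mm,
      normalization = config$normalization)
  })
  write_region_gene_matrix(expr_build$matrix,
                           file.path(out_dir, "expression_matrix.tsv"))
  register("expression_matrix", file.path(out_dir, "expression_matrix.tsv"))

  pls_results <- list()
  cluster_tables <- list()
  modality_summaries <- list()
  seed_offset <- 0L
  for (mn in names(config$modalities)) {
    mod <- config$modalities[[mn]]
    res <- run_stage(paste0("imaging:", mn), {
      manifest <- read_manifest(mod$manifest)
      maps <- lapply(manifest$path, function(p) {
        vol <- read_volume(p, tr = mod$tr)
        if (identical(mod$kind, "bold")) {
          vol <- compute_alff(vol, mask, band = config$band)
        } else {
          vol <- zscore_volume(vol, mask)
        }
        gaussian_smooth(vol, config$fwhm, mask = mask)
      })
      design <- dplyr::mutate(
        manifest, group = as.integer(.data$group == .data$group[1]))
      # group coding: 1 = first-listed group (patients in the demo)
      fit <- fit_group_glm(maps, design, mask,
                           covariates = c("age", "sex", "mean_fd"))
      fit <- estimate_smoothness(fit)
      clusters <- grf_cluster_correct(fit, voxel_p = config$voxel_p,
                                      cluster_p = config$cluster_p)
      list(fit = fit, clusters = clusters, manifest = manifest)
    })
    write_volume(res$fit$t, file.path(out_dir, paste0(mn, "_tmap.nii.gz")))
    register(paste0(mn, "_tmap"), file.path(out_dir, paste0(mn, "_tmap.nii.gz")))
    readr::write_tsv(dplyr::select(res$clusters, -"voxels"),
                     file.path(out_dir, paste0(mn, "_clusters.tsv")))
    register(paste0(mn, "_clusters"),
             file.path(out_dir, paste0(mn, "_clusters.tsv")))

    pls <- run_stage(paste0("pls:", mn), {
      rv <- regionalize_effect_map(res$fit$t, atlas, mask)
      pls_transcriptomics(expr_build$matrix, rv,
                          n_perm = config$n_perm, n_boot = config$n_boot,
                          seed = config$seed + seed_offset,
                          alpha = config$alpha)
    })
    seed_offset <- seed_offset + 2L
    readr::write_tsv(tidy(pls), file.path(out_dir, paste0(mn, "_genes.tsv")))
    register(paste0(mn, "_genes"), file.path(out_dir, paste0(mn, "_genes.tsv")))
    readr::write_tsv(pls$scores, file.path(out_dir, paste0(mn, "_scores.tsv")))
    register(paste0(mn, "_scores"), file.path(out_dir, paste0(mn, "_scores.tsv")))
    pls_results[[mn]] <- pls
    cluster_tables[[mn]] <- res$clusters
    modality_summaries[[mn]] <- list(
      n_surviving_clusters = nrow(res$clusters),
      spatial_r = pls$r, permutation_p = pls$perm$p,
      n_selected_genes = length(pls$selected))
  }

  overlap <- NULL
  if (length(pls_results) >= 2L) {
    nm <- names(pls_results)[1:2]
    overlap <- run_stage("overlap", {
      select_and_overlap(pls_results[[nm[1]]], pls_results[[nm[2]]],
                         alpha = config$alpha,
                         tag_a = nm[1], tag_b = nm[2])
    })
    readr::write_tsv(dplyr::bind_rows(overlap$set_a, overlap$set_b,
                                      overlap$overlap),
                     file.path(out_dir, "gene_sets.tsv"))
    register("gene_sets", file.path(out_dir, "gene_sets.tsv"))
  }

  enrichment_tables <- list()
  if (!is.null(config$gmt)) {
    annot <- run_stage("annotations", {
      gmt <- config$gmt
      if (is.null(names(gmt))) names(gmt) <- paste0("SET", seq_along(gmt))
      dplyr::bind_rows(lapply(names(gmt), function(cat) {
        read_gmt(gmt[[cat]], category = cat)
      }))
    })
    universe <- expr_build$retained_genes
    for (mn in names(pls_results)) {
      tab <- run_stage(paste0("enrichment:", mn), {
        enrich(pls_results[[mn]]$selected, universe, annot,
               min_overlap = config$min_overlap)
      })
      readr::write_tsv(tab, file.path(out_dir, paste0(mn, "_enrichment.tsv")))
      register(paste0(mn, "_enrichment"),
               file.path(out_dir, paste0(mn, "_enrichment.tsv")))
      enrichment_tables[[mn]] <- tab
    }
  }

  params <- config[setdiff(names(config), c("modalities", "donors", "gmt"))]
  manifest <- list(
    parameters = params,
    parameter_hash = rlang::hash(config),
    seed = config$seed,
    n_retained_genes = length(expr_build$retained_genes),
    modalities = modality_summaries,
    overlap = if (is.null(overlap)) NULL else
      list(n_a = nrow(overlap$set_a), n_b = nrow(overlap$set_b),
           n_overlap = nrow(overlap$overlap),
           hypergeometric_p = overlap$overlap_p),
    outputs = outputs
  )
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  manifest$pls_results <- pls_results
  manifest$clusters <- cluster_tables
  manifest$enrichment <- enrichment_tables
  invisible(manifest)
}

#' Score recovery of planted effect regions
#'
#' Fraction of the planted regions that intersect a surviving cluster.
#'
#' @param clusters Cluster tibble from [grf_cluster_correct()] (needs the
#'   `voxels` list-column).
#' @param atlas The [parcellation_atlas] the effects were planted on.
#' @param effect_regions Integer IDs of the planted regions.
#' @return Tibble: `n_planted`, `n_recovered`, `recovery`,
#'   `recovered_ids` (list).
#' @export
score_region_recovery <- function(clusters, atlas, effect_regions) {
  lab <- vol_data(atlas$labels)
  hit <- integer()
  if (nrow(clusters)) {
    hit <- unique(unlist(lapply(clusters$voxels, function(v) lab[v])))
  }
  rec <- intersect(effect_regions, hit)
  tibble(n_planted = length(effect_regions), n_recovered = length(rec),
         recovery = length(rec) / max(1L, length(effect_regions)),
         recovered_ids = list(rec))
}

#' Score recovery of planted loading genes
#'
#' Sensitivity and observed false-discovery proportion of a selected gene
#' set against the generator's loading genes.
#'
#' @param selected Character vector of selected gene IDs.
#' @param truth Truth object from [generate_donor_expression()].
#' @param universe Gene universe actually tested (defaults to all truth
#'   genes).
#' @return Tibble: `n_selected`, `sensitivity`, `fdr`.
#' @export
score_gene_recovery <- function(selected, truth, universe = truth$gene_ids) {
  loading <- intersect(truth$loading_genes, universe)
  tp <- length(intersect(selected, loading))
  tibble(n_selected = length(selected),
         sensitivity = if (length(loading)) tp / length(loading) else NA_real_,
         fdr = if (length(selected)) 1 - tp / length(selected) else 0)
}
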