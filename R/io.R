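#' Write / read a donor sample table
#'
#' Tab-separated: `donor_id`, `x_mm`, `y_mm`, `z_mm`, then one column per
#' gene.
#'
#' @param donor A [donor_expression].
#' @param path Output TSV path.
#' @return `path` invisibly (write) or a [donor_expression] (read).
#' @export
write_donor_table <- function(donor, path) {
  stopifnot(inherits(donor, "donor_expression"))
  tab <- dplyr::bind_cols(
    tibble(donor_id = donor$donor_id,
           x_mm = donor$coords[, 1], y_mm = donor$coords[, 2],
           z_mm = donor$coords[, 3]),
    as_tibble(donor$expr, .name_repair = "minimal") |>
      setNames(donor$gene_ids)
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_donor_table
#' @export
read_donor_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- c("donor_id", "x_mm", "y_mm", "z_mm")
  if (!all(meta %in% names(tab))) {
    abort("Donor table needs donor_id, x_mm, y_mm, z_mm columns.")
  }
  gene_ids <- setdiff(names(tab), meta)
  donor_expression(donor_id = tab$donor_id[1],
                   coords = as.matrix(tab[, c("x_mm", "y_mm", "z_mm")]),
                   expr = as.matrix(tab[, gene_ids]),
                   gene_ids = gene_ids)
}

#' Write / read a region-by-gene matrix as TSV
#'
#' @param x A [region_gene_matrix].
#' @param path TSV path (`region_id` column plus one column per gene).
#' @return `path` invisibly (write) or a [region_gene_matrix] (read).
#' @export
write_region_gene_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_region_gene_matrix
#' @export
read_region_gene_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"region_id" %in% names(tab)) abort("Missing region_id column.")
  genes <- setdiff(names(tab), "region_id")
  region_gene_matrix(tab$region_id, genes, as.matrix(tab[, genes]))
}

#' Write an atlas region table
#' @param atlas A [parcellation_atlas].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(atlas, path) {
  readr::write_tsv(atlas$regions, path)
  invisible(path)
}
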