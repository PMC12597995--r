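#' Plot a PLS spatial association
#'
#' Scatter of regional PLS1 scores against the regional phenotype map,
#' with the fitted spatial correlation in the subtitle.
#'
#' @param object A `pls_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pls_result
#' @export
autoplot.pls_result <- function(object, ...) {
  df <- tibble(score = object$scores$value, target = object$y)
  lab <- sprintf("spatial r = %.3f%s", object$r,
                 if (!is.null(object$perm))
                   sprintf(", permutation p = %.2g", object$perm$p) else "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$target)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = "PLS1 region score", y = "Regional effect (t)",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Ranked PLS gene weights
#'
#' @param result A bootstrapped `pls_result`.
#' @param alpha Highlight genes with bootstrap `p < alpha`.
#' @return A ggplot object.
#' @export
plot_gene_weights <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "pls_result"), !is.null(result$boot))
  df <- dplyr::arrange(result$boot$genes, dplyr::desc(.data$weight))
  df$rank <- seq_len(nrow(df))
  df$selected <- df$p < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$weight,
                                   colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey60"),
                                 name = sprintf("p < %.2g", alpha)) +
    ggplot2::labs(x = "Gene rank", y = "PLS1 weight") +
    ggplot2::theme_minimal()
}

#' Enrichment bubble plot
#'
#' Fold enrichment on the x axis, terms on the y axis, bubble size =
#' overlap count, colour = -log10(p); one panel per category.
#'
#' @param records Enrichment tibble from [enrich()].
#' @param top_n Terms shown per category (by p).
#' @param q_max Keep records with `q` at or below this (default 1 shows
#'   all).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(records, top_n = 10, q_max = 1) {
  df <- dplyr::filter(records, .data$q <= q_max)
  df <- dplyr::slice_min(df, .data$p, n = top_n, by = "category",
                         with_ties = FALSE)
  if (!nrow(df)) abort("Nothing to plot at this q threshold.")
  df$name <- stats::reorder(df$name, df$fold_enrichment)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment, y = .data$name,
                                   size = .data$k,
                                   colour = -log10(.data$p))) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_colour_viridis_c(name = "-log10(p)") +
    ggplot2::scale_size_continuous(name = "genes") +
    ggplot2::labs(x = "Fold enrichment", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
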