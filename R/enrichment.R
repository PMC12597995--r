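#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated — term ID, description,
#' then member genes. Duplicate members within a term are dropped.
#'
#' @param path Path to a GMT file.
#' @param category Category label for every term in the file (`"BP"`,
#'   `"CC"`, `"MF"`, `"PATHWAY"`, ...).
#' @return Annotation tibble: `term_id`, `name`, `category`, `genes`
#'   (list-column).
#' @export
read_gmt <- function(path, category = "BP") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort(sprintf("GMT parse error at line %d: fewer than 3 fields.", i))
    }
    tibble(term_id = fields[1], name = fields[2], category = category,
           genes = list(unique(fields[-(1:2)])))
  })
  coll <- dplyr::bind_rows(out)
  if (anyDuplicated(coll$term_id)) abort("Duplicate term IDs in GMT file.")
  coll
}

#' Write an annotation collection as GMT
#'
#' @param collection Annotation tibble (`term_id`, `name`, `genes`
#'   list-column); the category column is not representable in GMT and is
#'   dropped — write one file per category.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$term_id[i], collection$name[i],
            collection$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each term: `k` = hits (selected genes in the term), `n` = set
#' size, `K` = term size within the universe, `N` = universe size;
#' fold enrichment `(k/n)/(K/N)`; one-sided hypergeometric tail
#' `P(X >= k)` (or the EASE variant, the tail at `k - 1`); BH-FDR within
#' each category by default. Terms are intersected with the universe
#' before testing and records with `k < min_overlap` are excluded before
#' the FDR step.
#'
#' @param genes Character vector of selected gene IDs (or a tibble with a
#'   `gene_id` column), a subset of `universe`.
#' @param universe Character vector: the tested gene population (e.g. the
#'   post-stability-filter gene list).
#' @param annotations Annotation tibble from [read_gmt()] /
#'   [generate_annotation()].
#' @param min_overlap Minimum hits per term (default 2).
#' @param ease Use the EASE score (hypergeometric tail at `k - 1`).
#' @param fdr_scope `"category"` (default) or `"global"`.
#' @return Tibble of enrichment records: `category`, `term_id`, `name`,
#'   `k`, `n`, `K`, `N`, `fold_enrichment`, `p`, `q`, ordered by `p`
#'   within category.
#' @export
enrich <- function(genes, universe, annotations, min_overlap = 2,
                   ease = FALSE, fdr_scope = c("category", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  if (is.data.frame(genes)) genes <- genes$gene_id
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  if (!length(universe)) abort("Empty gene universe.")
  if (!all(genes %in% universe)) {
    abort("Selected genes must be a subset of the universe.")
  }
  n <- length(genes)
  n_univ <- length(universe)
  recs <- lapply(seq_len(nrow(annotations)), function(i) {
    members <- intersect(annotations$genes[[i]], universe)
    big_k <- length(members)
    if (big_k == 0L) return(NULL)
    k <- length(intersect(genes, members))
    fold <- if (n == 0) 0 else (k / n) / (big_k / n_univ)
    k_tail <- if (ease) max(k - 1L, 0L) else k
    p <- phyper(k_tail - 1, big_k, n_univ - big_k, n, lower.tail = FALSE)
    tibble(category = annotations$category[i],
           term_id = annotations$term_id[i],
           name = annotations$name[i],
           k = k, n = n, K = big_k, N = n_univ,
           fold_enrichment = fold, p = p)
  })
  out <- dplyr::bind_rows(recs)
  if (!nrow(out)) {
    return(tibble(category = character(), term_id = character(),
                  name = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), fold_enrichment = numeric(),
                  p = numeric(), q = numeric()))
  }
  out <- dplyr::filter(out, .data$k >= min_overlap)
  if (fdr_scope == "category") {
    out <- dplyr::mutate(out, q = p.adjust(.data$p, method = "BH"),
                         .by = "category")
  } else {
    out <- dplyr::mutate(out, q = p.adjust(.data$p, method = "BH"))
  }
  dplyr::arrange(out, .data$category, .data$p)
}
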