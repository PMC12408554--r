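#' Ensemble-based gene category enrichment analysis
#'
#' Aggregates gene scores at the category level (mean score of the annotated
#' genes, restricted to categories with `min_size`–`max_size` scored
#' members) and judges each category against a neuroimaging-spatial
#' ensemble null: for every surrogate map in the ensemble, gene scores and
#' category scores are recomputed, giving a per-category null distribution.
#' The two-sided p-value uses the add-one estimator
#' `p = 2 * min((1 + #\{null >= obs\}) / (S + 1),
#' (1 + #\{null <= obs\}) / (S + 1))`, capped at 1 — conservative and never
#' zero. Null gene scores for all surrogates are computed as a single
#' standardized cross-product, which keeps thousands of surrogates
#' tractable.
#'
#' @param scores Gene score tibble from [gene_scores()] (computed on the
#'   original map).
#' @param annotations Long annotation tibble (`category_id`, `aspect`,
#'   `gene`) from [read_annotations()] or a synthetic bundle.
#' @param expr A `gene_expression_matrix` (or samples x genes matrix with
#'   sample-id rownames); must cover the ensemble's samples.
#' @param samples The `spatial_samples` the ensemble was generated from.
#' @param ensemble A `surrogate_ensemble` over the same sample geometry.
#' @param min_size,max_size Category size bounds among scored genes
#'   (defaults 10 and 200).
#' @return A `category_result` tibble with columns `category_id`, `aspect`,
#'   `n_genes`, `observed_score`, `null_mean`, `null_sd`, `p`, `direction`,
#'   sorted by `p`. Categories excluded by the size filter are counted in
#'   attribute `n_excluded`.
#' @export
gcea <- function(scores, annotations, expr, samples, ensemble,
                 min_size = 10L, max_size = 200L) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  if (!identical(ensemble$sample_id, samples$sample_id))
    stop("ensemble was generated from a different sample set", call. = FALSE)
  scored <- scores[is.finite(scores$score), ]
  ann <- annotations[annotations$gene %in% scored$gene, ]
  sizes <- dplyr::summarise(dplyr::group_by(ann, .data$category_id),
                            aspect = .data$aspect[1],
                            n_genes = dplyr::n_distinct(.data$gene))
  keep <- sizes$n_genes >= min_size & sizes$n_genes <= max_size
  n_excluded <- sum(!keep)
  sizes <- sizes[keep, ]
  if (!nrow(sizes)) stop("no category passes the size filter", call. = FALSE)
  ann <- ann[ann$category_id %in% sizes$category_id, ]

  values <- if (inherits(expr, "gene_expression_matrix")) expr$values else expr
  ids <- rownames(values) %||% expr$samples$sample_id
  m <- match(samples$sample_id, ids)
  if (anyNA(m)) stop("ensemble samples missing from the expression matrix",
                     call. = FALSE)
  values <- values[m, , drop = FALSE]

  # null gene scores for all surrogates in one pass: G x S
  null_gene <- gene_score_matrix(values, t(ensemble$maps))
  rownames(null_gene) <- colnames(values)

  obs <- stats::setNames(scored$score, scored$gene)
  cats <- sizes$category_id
  member <- split(unique(ann[c("category_id", "gene")])$gene,
                  unique(ann[c("category_id", "gene")])$category_id)[cats]
  res <- purrr::map_dfr(cats, function(cid) {
    genes <- member[[cid]]
    null_cat <- colMeans(null_gene[genes, , drop = FALSE])
    ok <- is.finite(null_cat)
    null_cat <- null_cat[ok]
    S <- length(null_cat)
    o <- mean(obs[genes])
    p <- 2 * min((1 + sum(null_cat >= o)) / (S + 1),
                 (1 + sum(null_cat <= o)) / (S + 1))
    tibble::tibble(category_id = cid,
                   observed_score = o,
                   null_mean = mean(null_cat), null_sd = stats::sd(null_cat),
                   p = min(p, 1),
                   direction = if (o >= mean(null_cat)) "positive" else "negative")
  })
  out <- dplyr::arrange(dplyr::inner_join(sizes, res, by = "category_id"),
                        .data$p)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_surrogate") <- nrow(ensemble$maps)
  class(out) <- c("category_result", class(out))
  out
}
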