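#' Plot an axial slice of a stat map
#'
#' @param map A `stat_map`.
#' @param k 0-based axial slice index; defaults to the middle slice.
#' @return A ggplot object.
#' @export
plot_slice <- function(map, k = NULL) {
  stopifnot(inherits(map, "stat_map"))
  dims <- grid_dims(map)
  if (is.null(k)) k <- dims[3] %/% 2L
  df <- as_tibble_statmap(map)
  df <- df[df$k == k, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey95",
                                  high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s map, axial slice k = %d", map$kind, k),
                  x = "x (mm)", y = "y (mm)", fill = "value") +
    ggplot2::theme_minimal()
}

#' @method autoplot stat_map
#' @export
autoplot.stat_map <- function(object, ...) plot_slice(object, ...)

#' Null distribution and observed cluster sizes of a permutation fit
#'
#' @param object A `cluster_fwe` object.
#' @param ... Unused.
#' @return A ggplot object: per-tail histogram of permutation maximum
#'   cluster sizes with the observed cluster sizes overlaid.
#' @method autoplot cluster_fwe
#' @export
autoplot.cluster_fwe <- function(object, ...) {
  null_df <- tibble::tibble(
    tail = rep(c("pos", "neg"), each = nrow(object$null_max)),
    max_size = c(object$null_max[, "pos"], object$null_max[, "neg"]))
  p <- ggplot2::ggplot(null_df, ggplot2::aes(.data$max_size)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::facet_wrap(~tail) +
    ggplot2::labs(x = "max cluster size under permutation",
                  y = "count",
                  title = sprintf("Cluster-FWE null (%d permutations)",
                                  object$n_perm)) +
    ggplot2::theme_minimal()
  if (nrow(object$clusters))
    p <- p + ggplot2::geom_vline(
      data = dplyr::select(object$clusters, "tail", "size"),
      ggplot2::aes(xintercept = .data$size), colour = "#b2182b",
      linetype = 2)
  p
}

#' Dot plot of enriched gene categories
#'
#' Category mean score on the x axis, categories ordered by significance on
#' the y axis, colour encoding -log10(p), shape encoding the direction
#' relative to the ensemble null.
#'
#' @param object A `category_result` tibble from [gcea()].
#' @param max_categories Show at most this many top categories (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot category_result
#' @export
autoplot.category_result <- function(object, max_categories = 30, ...) {
  df <- utils::head(dplyr::arrange(object, .data$p), max_categories)
  df$category_id <- factor(df$category_id,
                           levels = rev(unique(df$category_id)))
  ggplot2::ggplot(df, ggplot2::aes(.data$observed_score, .data$category_id,
                                   colour = -log10(.data$p),
                                   shape = .data$direction)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(positive = 17, negative = 16)) +
    ggplot2::labs(x = "category score (mean gene score)", y = NULL,
                  colour = "-log10(p)", shape = "direction") +
    ggplot2::theme_minimal()
}

#' Receptor correlation profile plot
#'
#' @param object A `neuromap_result` tibble from [neuromap_association()].
#' @param alpha Significance level to highlight (default 0.05).
#' @param ... Unused.
#' @return A ggplot object of partial correlations per receptor map.
#' @method autoplot neuromap_result
#' @export
autoplot.neuromap_result <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(object, significant = .data$p_perm < alpha)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$map_name, .data$r_partial),
                                   .data$r_partial, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey70")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "GM-adjusted spatial r",
                  fill = sprintf("p < %g", alpha)) +
    ggplot2::theme_minimal()
}
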