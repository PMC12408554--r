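#' Mean map value inside a cluster
#'
#' Unweighted mean of the finite in-cluster voxel values — the per-subject
#' imaging summary (e.g. mean fALFF z over the precuneus cluster) that enters
#' the clinical correlations.
#'
#' @param map A `stat_map`.
#' @param cluster A `brain_mask` of the cluster, same grid as `map`.
#' @return A single numeric value.
#' @export
cluster_mean <- function(map, cluster) {
  stopifnot(inherits(map, "stat_map"), inherits(cluster, "brain_mask"))
  stopifnot_same_grid(map, cluster, "map and cluster")
  v <- map$data[cluster$data]
  v <- v[is.finite(v)]
  if (!length(v)) stop("cluster has no finite voxels in the map", call. = FALSE)
  mean(v)
}

#' Pearson correlation coefficient
#'
#' Standard product-moment coefficient; errors on degenerate input rather
#' than returning `NA`.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, nonzero variance.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input", call. = FALSE)
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' The analytic test used for the clinical correlations: `t = r *
#' sqrt(n - 2) / sqrt(1 - r^2)` referred to a Student t distribution with
#' `n - 2` degrees of freedom, two-sided. `|r| = 1` returns `p = 0` as the
#' limiting convention.
#'
#' @param r Correlation coefficient.
#' @param n Sample size (>= 3).
#' @return Two-sided p-value.
#' @export
pearson_p <- function(r, n) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1", call. = FALSE)
  if (any(n < 3)) stop("`n` must be >= 3", call. = FALSE)
  out <- rep(0, length(r))
  ok <- abs(r) < 1
  tstat <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  out[ok] <- 2 * stats::pt(-abs(tstat), n - 2)
  out
}

#' Correlate cluster-level imaging summaries with burnout subscales
#'
#' For each imaging measure column and each Maslach Burnout Inventory
#' subscale (EE, DP, PA), computes the plain Pearson correlation and its
#' analytic two-sided p-value over the supplied subjects (typically the
#' burnout group only, matching the study design). No covariate adjustment is
#' applied; Benjamini–Hochberg correction across the table is available
#' behind `adjust = "BH"` but off by default (uncorrected p is reported).
#'
#' @param data Tibble with one row per subject containing the imaging
#'   measure columns and the score columns.
#' @param measures Character vector of imaging measure column names.
#' @param scores Character vector of score columns; default `c("ee", "dp",
#'   "pa")`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with columns `imaging_measure`, `score`, `r`, `n`, `p`
#'   (and `p_adj` when `adjust = "BH"`).
#' @export
clinical_association <- function(data, measures, scores = c("ee", "dp", "pa"),
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(measures %in% names(data)), all(scores %in% names(data)))
  grid <- tidyr::expand_grid(imaging_measure = measures, score = scores)
  out <- purrr::pmap_dfr(grid, function(imaging_measure, score) {
    x <- data[[imaging_measure]]
    y <- data[[score]]
    keep <- is.finite(x) & is.finite(y)
    r <- pearson_r(x[keep], y[keep])
    tibble::tibble(imaging_measure = imaging_measure, score = score,
                   r = r, n = sum(keep), p = pearson_p(r, sum(keep)))
  })
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
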