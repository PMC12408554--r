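#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a permutation cluster-FWE fit
#'
#' @param x A `cluster_fwe` object.
#' @param ... Unused.
#' @return One row per cluster: id, tail, size, peak t, peak MNI mm
#'   coordinates, and the FWE-corrected p-value.
#' @method tidy cluster_fwe
#' @export
tidy.cluster_fwe <- function(x, ...) {
  dplyr::select(x$clusters, -"voxels")
}

#' @rdname tidy.cluster_fwe
#' @method glance cluster_fwe
#' @export
glance.cluster_fwe <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$p_fwe < x$alpha_fwe),
                 df = x$df, voxel_p = x$voxel_p, alpha_fwe = x$alpha_fwe,
                 n_perm = x$n_perm, connectivity = x$connectivity,
                 seed = x$seed)
}

#' Tidy a spatial-lag fit
#'
#' @param x A `spatial_lag_fit` object.
#' @param ... Unused.
#' @return `tidy()`: the parameter estimates; `glance()`: fit summary.
#' @method tidy spatial_lag_fit
#' @export
tidy.spatial_lag_fit <- function(x, ...) {
  tibble::tibble(term = c("rho", "d0"), estimate = c(x$rho, x$d0))
}

#' @rdname tidy.spatial_lag_fit
#' @method glance spatial_lag_fit
#' @export
glance.spatial_lag_fit <- function(x, ...) {
  tibble::tibble(rho = x$rho, d0 = x$d0, sse = x$sse,
                 n_locations = nrow(x$coords),
                 n_candidates = nrow(x$grid), seed = x$seed)
}
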