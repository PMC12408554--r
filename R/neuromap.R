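#' Region-mean profile of a map over a parcellation
#'
#' Unweighted mean of the finite map voxels in each atlas region. Regions
#' with no finite voxel get `NA` (excluded pairwise downstream).
#'
#' @param map A `stat_map`.
#' @param parc A `parcellation` on the same grid.
#' @return A tibble with columns `region_id`, `name`, `value`, `n_voxels`.
#' @export
parcellate <- function(map, parc) {
  stopifnot(inherits(map, "stat_map"), inherits(parc, "parcellation"))
  stopifnot_same_grid(map, parc, "map and parcellation")
  lab <- as.vector(parc$labels)
  val <- as.vector(map$data)
  use <- lab > 0L & is.finite(val)
  if (!any(use)) stop("no finite voxels overlap the parcellation",
                      call. = FALSE)
  sums <- rowsum(val[use], lab[use])
  counts <- table(lab[use])
  means <- stats::setNames(rep(NA_real_, length(parc$region_ids)),
                           parc$region_ids)
  nvox <- stats::setNames(rep(0L, length(parc$region_ids)), parc$region_ids)
  means[rownames(sums)] <- sums[, 1] / as.vector(counts)
  nvox[names(counts)] <- as.vector(counts)
  tibble::tibble(region_id = parc$region_ids, name = parc$names,
                 value = unname(means), n_voxels = unname(nvox))
}

#' Region centroids of a parcellation in MNI mm
#'
#' @param parc A `parcellation`.
#' @return A tibble with columns `region_id`, `x`, `y`, `z`.
#' @export
region_centroids <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  idx <- which(parc$labels > 0L)
  mm <- voxel_to_world(arrayInd(idx, dim(parc$labels)) - 1L, parc$affine)
  lab <- parc$labels[idx]
  cx <- rowsum(mm, lab) / as.vector(table(lab))
  tibble::tibble(region_id = as.integer(rownames(cx)),
                 x = cx[, 1], y = cx[, 2], z = cx[, 3])
}

#' Gray-matter-adjusted spatial partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' linearly regressed (with intercept) on the region-mean gray-matter
#' probability — the partial-volume adjustment of the cross-regional
#' receptor analysis. Equals the plain Pearson correlation when `gm` is
#' constant.
#'
#' @param x,y,gm Numeric region-value vectors of equal length (>=
#'   `min_regions` complete regions after pairwise NA removal).
#' @param min_regions Minimum shared regions (default 10).
#' @return The partial correlation coefficient. A vector that is an exact
#'   linear function of `gm` has a numerically zero residual and is
#'   orthogonal to everything: the result is 0.
#' @export
partial_spatial_corr <- function(x, y, gm, min_regions = 10L) {
  stopifnot(length(x) == length(y), length(x) == length(gm))
  keep <- is.finite(x) & is.finite(y) & is.finite(gm)
  if (sum(keep) < min_regions)
    stop("need at least ", min_regions, " shared regions", call. = FALSE)
  x <- x[keep]; y <- y[keep]; gm <- gm[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance region vector", call. = FALSE)
  resid_on <- function(v) {
    if (stats::sd(gm) == 0) return(v - mean(v))
    Z <- cbind(1, gm)
    drop(v - Z %*% solve(crossprod(Z), crossprod(Z, v)))
  }
  rx <- resid_on(x); ry <- resid_on(y)
  # fully gm-explained vectors are orthogonal to every residual
  if (stats::sd(rx) < 1e-10 * stats::sd(x) ||
      stats::sd(ry) < 1e-10 * stats::sd(y)) return(0)
  stats::cor(rx, ry)
}

#' Spatially constrained permutation p-value for a receptor correlation
#'
#' The observed statistic is the gray-matter-adjusted partial correlation
#' between the t-map region profile and the receptor region profile. The
#' null draws the same statistic with the t-map profile replaced by each
#' autocorrelation-preserving surrogate in the ensemble:
#' `p = (1 + #\{|null r| >= |observed r|\}) / (n_perm + 1)` (two-sided on
#' `|r|`).
#'
#' @param x Observed t-map region vector (the ensemble's original map).
#' @param y Receptor region vector.
#' @param gm Region-mean gray-matter probability vector.
#' @param ensemble A `surrogate_ensemble` built from `x` at the region
#'   centroids.
#' @param map_name Optional label for the output row.
#' @param min_regions Minimum shared regions (default 10).
#' @return A one-row tibble: `map_name`, `r_partial`, `p_perm`, `n_perm`.
#' @export
neuromap_permutation_p <- function(x, y, gm, ensemble, map_name = "receptor",
                                   min_regions = 10L) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  n_perm <- nrow(ensemble$maps)
  if (n_perm < 100) warning("fewer than 100 permutations; p is coarse")
  if (ncol(ensemble$maps) != length(x))
    stop("ensemble geometry does not match the region vector", call. = FALSE)
  obs <- partial_spatial_corr(x, y, gm, min_regions)
  null_r <- vapply(seq_len(n_perm), function(k) {
    partial_spatial_corr(ensemble$maps[k, ], y, gm, min_regions)
  }, double(1))
  tibble::tibble(map_name = map_name, r_partial = obs,
                 p_perm = (1 + sum(abs(null_r) >= abs(obs))) / (n_perm + 1),
                 n_perm = n_perm)
}

#' Receptor/transporter spatial correlation analysis
#'
#' Parcellates the group t-map, the gray-matter probability map, and each
#' receptor density map over the atlas; fits a spatial-lag model to the
#' t-map region profile at the region centroids; generates one
#' autocorrelation-preserving surrogate ensemble; and reports the
#' gray-matter-adjusted partial correlation and spatially constrained
#' permutation p-value for every receptor map.
#'
#' @param tmap Group t-map (`stat_map`).
#' @param receptors Named list of receptor `stat_map`s.
#' @param gm_map Gray-matter probability `stat_map`.
#' @param parc Atlas `parcellation` (90 regions in the emulated study).
#' @param n_perm Number of surrogate permutations (default 5000).
#' @param seed Integer seed.
#' @param fit Optional precomputed `spatial_lag_fit` for the t-map profile.
#' @param generator Surrogate generator for the null ensemble; defaults to
#'   `"variogram_match"`, which reproduces the region profile's empirical
#'   variogram more faithfully than the lag model on centroid geometries.
#' @return A `neuromap_result` tibble: one row per receptor map with
#'   `map_name`, `r_partial`, `p_perm`, `n_perm`.
#' @export
neuromap_association <- function(tmap, receptors, gm_map, parc,
                                 n_perm = 5000L, seed = 1L, fit = NULL,
                                 generator = "variogram_match") {
  stopifnot(is.list(receptors), length(receptors) >= 1L)
  xr <- parcellate(tmap, parc)
  gmr <- parcellate(gm_map, parc)
  cents <- region_centroids(parc)
  keep <- is.finite(xr$value)
  samples <- tibble::tibble(sample_id = as.character(xr$region_id[keep]),
                            x = cents$x[match(xr$region_id[keep], cents$region_id)],
                            y = cents$y[match(xr$region_id[keep], cents$region_id)],
                            z = cents$z[match(xr$region_id[keep], cents$region_id)],
                            value = xr$value[keep])
  class(samples) <- c("spatial_samples", class(samples))
  if (is.null(fit)) fit <- fit_spatial_lag(samples, seed = seed,
                                           generator = generator)
  ensemble <- generate_surrogates(samples, fit, n_surrogate = n_perm,
                                  seed = seed)
  nm <- names(receptors) %||% paste0("map_", seq_along(receptors))
  out <- purrr::map_dfr(seq_along(receptors), function(i) {
    yr <- parcellate(receptors[[i]], parc)
    neuromap_permutation_p(samples$value,
                           yr$value[match(xr$region_id[keep], yr$region_id)],
                           gmr$value[match(xr$region_id[keep], gmr$region_id)],
                           ensemble, map_name = nm[i])
  })
  attr(out, "fit") <- fit
  class(out) <- c("neuromap_result", class(out))
  out
}
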