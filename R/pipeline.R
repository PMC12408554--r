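#' Group fALFF analysis: maps, GLM, permutation cluster FWE
#'
#' Convenience wrapper chaining the per-subject steps: compute the fALFF map
#' of every volume, Fisher z-standardize, build the covariate-adjusted
#' design, and run [permutation_cluster_fwe()].
#'
#' @param volumes List of `volume4d`, ordered like `subjects`.
#' @param mask Analysis `brain_mask`.
#' @param subjects Subject tibble ([load_subject_table()] /
#'   [gen_bold_cohort()]).
#' @param band A [band_spec()].
#' @param standardize `"fisher"` (default), `"zscore"`, or `"none"`.
#' @param ... Passed to [permutation_cluster_fwe()] (`voxel_p`, `n_perm`,
#'   `connectivity`, `seed`, ...).
#' @return A list with `maps` (per-subject standardized fALFF `stat_map`s)
#'   and `fwe` (the `cluster_fwe` fit).
#' @export
falff_group_analysis <- function(volumes, mask, subjects,
                                 band = band_spec(),
                                 standardize = c("fisher", "zscore", "none"),
                                 ...) {
  standardize <- match.arg(standardize)
  maps <- lapply(volumes, function(v) {
    m <- falff_map(v, mask, band)
    if (standardize != "none") m <- fisher_z_standardize(m, standardize)
    m
  })
  design <- build_design(subjects)
  list(maps = maps, fwe = permutation_cluster_fwe(maps, design, mask, ...))
}

#' Group seed-FC analysis
#'
#' Computes each subject's Fisher-z seed connectivity map from a seed region
#' (typically a significant fALFF cluster) and runs the same
#' covariate-adjusted permutation cluster-FWE inference.
#'
#' @inheritParams falff_group_analysis
#' @param seed_region A `brain_mask` of the seed voxels.
#' @return A list with `maps` (per-subject `fc_z` maps) and `fwe`.
#' @export
fc_group_analysis <- function(volumes, seed_region, mask, subjects, ...) {
  maps <- lapply(volumes, seed_fc_map, seed = seed_region, mask = mask)
  design <- build_design(subjects)
  list(maps = maps, fwe = permutation_cluster_fwe(maps, design, mask, ...))
}
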