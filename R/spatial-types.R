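#' Spatial container types
#'
#' `burnoutmap` represents images as lightweight S3 wrappers around plain R
#' arrays plus a 4x4 voxel-to-world affine in MNI millimetres. Voxel indices
#' are 0-based in all world-coordinate computations (the NIfTI convention);
#' R's 1-based array subscripts are converted internally.
#'
#' * `volume4d()` — a subject's 4D BOLD grid with repetition time `tr` (s).
#' * `stat_map()` — a 3D scalar map (fALFF z, FC z, group t, receptor density,
#'   or gray-matter probability), tagged with its `kind`.
#' * `brain_mask()` — a logical 3D grid selecting analysis voxels.
#' * `parcellation()` — an integer-labelled 3D grid (0 = background) with the
#'   region ids and names of an AAL-90-style atlas.
#'
#' @param data Numeric array of the stated dimensionality.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @param tr Repetition time in seconds (4D volumes).
#' @param kind One of `"falff_z"`, `"fc_z"`, `"tmap"`, `"receptor"`,
#'   `"gm_prob"`.
#' @param labels Integer 3D array of region labels, 0 for background.
#' @param region_ids Integer vector of the positive region ids in use.
#' @param names Character vector of region names, parallel to `region_ids`.
#'
#' @return An object of class `"volume4d"`, `"stat_map"`, `"brain_mask"`, or
#'   `"parcellation"`.
#' @name spatial-types
NULL

statmap_kinds <- c("falff_z", "fc_z", "tmap", "receptor", "gm_prob")

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  if (!all(is.finite(affine)))
    stop("`affine` must be finite", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("`affine` must be invertible", call. = FALSE)
  storage.mode(affine) <- "double"
  unname(affine)
}

#' @rdname spatial-types
#' @export
volume4d <- function(data, affine, tr) {
  if (length(dim(data)) != 4L)
    stop("expected 4D data, got ", length(dim(data)), "D", call. = FALSE)
  if (dim(data)[4] < 8L)
    stop("a 4D volume needs at least 8 timepoints", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a single positive number (seconds)", call. = FALSE)
  structure(list(data = data, affine = check_affine(affine), tr = tr),
            class = "volume4d")
}

#' @rdname spatial-types
#' @export
stat_map <- function(data, affine, kind = "tmap") {
  if (length(dim(data)) != 3L)
    stop("expected 3D data, got ", length(dim(data)), "D", call. = FALSE)
  kind <- match.arg(kind, statmap_kinds)
  structure(list(data = data, affine = check_affine(affine), kind = kind),
            class = "stat_map")
}

#' @rdname spatial-types
#' @export
brain_mask <- function(data, affine) {
  if (length(dim(data)) != 3L)
    stop("expected 3D data, got ", length(dim(data)), "D", call. = FALSE)
  data <- array(as.logical(data), dim(data))
  if (!any(data))
    stop("a brain mask needs at least one TRUE voxel", call. = FALSE)
  structure(list(data = data, affine = check_affine(affine)),
            class = "brain_mask")
}

#' @rdname spatial-types
#' @export
parcellation <- function(labels, affine, region_ids = NULL, names = NULL) {
  if (length(dim(labels)) != 3L)
    stop("expected 3D labels, got ", length(dim(labels)), "D", call. = FALSE)
  labels <- array(as.integer(round(labels)), dim(labels))
  present <- sort(unique(labels[labels != 0L]))
  if (is.null(region_ids)) region_ids <- present
  region_ids <- as.integer(region_ids)
  if (anyDuplicated(region_ids))
    stop("`region_ids` must be distinct", call. = FALSE)
  if (any(region_ids <= 0L))
    stop("`region_ids` must be positive", call. = FALSE)
  if (!all(present %in% region_ids))
    stop("labels contain ids absent from `region_ids`: ",
         paste(setdiff(present, region_ids), collapse = ", "), call. = FALSE)
  if (is.null(names)) names <- paste0("region_", region_ids)
  if (length(names) != length(region_ids))
    stop("`names` must be parallel to `region_ids`", call. = FALSE)
  structure(list(labels = labels, affine = check_affine(affine),
                 region_ids = region_ids, names = as.character(names)),
            class = "parcellation")
}

#' Convert between voxel indices and MNI world coordinates
#'
#' Voxel indices are 0-based, per the NIfTI convention; world coordinates are
#' MNI millimetres. Both accept a single coordinate (length-3 vector) or an
#' n x 3 matrix.
#'
#' @param vox,world Length-3 vector or n x 3 matrix of coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @return An n x 3 matrix of transformed coordinates.
#' @export
voxel_to_world <- function(vox, affine) {
  vox <- rbind2mat(vox)
  out <- cbind(vox, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(world, affine) {
  world <- rbind2mat(world)
  out <- cbind(world, 1) %*% t(solve(affine))
  out[, 1:3, drop = FALSE]
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns", call. = FALSE)
  x
}

grid_dims <- function(x) {
  d <- dim(if (is.null(x$data)) x$labels else x$data)
  d[1:3]
}

stopifnot_same_grid <- function(a, b, what = "objects") {
  if (!all(grid_dims(a) == grid_dims(b)) ||
      max(abs(a$affine - b$affine)) > 1e-6)
    stop(what, " must share the same grid and affine", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %dx%dx%d grid, %d timepoints, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$data)
  v <- x$data[is.finite(x$data)]
  cat(sprintf("<stat_map:%s> %dx%dx%d grid, %d finite voxels, range [%.3g, %.3g]\n",
              x$kind, d[1], d[2], d[3], length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_mask> %dx%dx%d grid, %d voxels in mask\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' @export
print.parcellation <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<parcellation> %dx%dx%d grid, %d regions\n",
              d[1], d[2], d[3], length(x$region_ids)))
  invisible(x)
}

#' Tabulate a stat map as a tibble of in-mask voxels
#'
#' Convenience for piping voxel values into dplyr/ggplot2: one row per voxel,
#' with 0-based voxel indices, MNI mm coordinates, and the value.
#'
#' @param map A `stat_map`.
#' @param mask Optional `brain_mask`; defaults to all finite voxels.
#' @return A tibble with columns `i, j, k, x, y, z, value`.
#' @export
as_tibble_statmap <- function(map, mask = NULL) {
  stopifnot(inherits(map, "stat_map"))
  keep <- if (is.null(mask)) is.finite(map$data) else mask$data
  idx <- which(keep)
  vox <- arrayInd(idx, dim(map$data)) - 1L
  mni <- voxel_to_world(vox, map$affine)
  tibble::tibble(i = vox[, 1], j = vox[, 2], k = vox[, 3],
                 x = mni[, 1], y = mni[, 2], z = mni[, 3],
                 value = map$data[idx])
}
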