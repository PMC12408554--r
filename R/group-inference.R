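#' Build the group-comparison design matrix
#'
#' One row per subject: intercept, group contrast (burnout = 1, control = 0),
#' and the nuisance covariates age, education, total intracranial volume
#' (TIV), BAI, and BDI. Row order follows the subject table.
#'
#' @param subjects Subject tibble as returned by [load_subject_table()] or
#'   [gen_bold_cohort()].
#' @param covariates Character vector of covariate columns to adjust for.
#'   Default matches the group analysis: age, education, tiv, bai, bdi. Use
#'   `character(0)` for an intercept + group design.
#' @return A numeric design matrix with attribute `contrast` naming the group
#'   column index.
#' @export
build_design <- function(subjects,
                         covariates = c("age", "education", "tiv", "bai", "bdi")) {
  stopifnot(all(c("group") %in% names(subjects)))
  g <- as.integer(as.character(subjects$group) == "burnout")
  if (length(unique(g)) < 2L)
    stop("both groups must be present", call. = FALSE)
  X <- cbind(intercept = 1, group = g)
  if (length(covariates)) {
    missing <- setdiff(covariates, names(subjects))
    if (length(missing))
      stop("missing covariate column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    X <- cbind(X, as.matrix(subjects[covariates]))
  }
  colnames(X) <- c("intercept", "group", covariates)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  structure(X, contrast = 2L)
}

# Core vectorized OLS t-statistics for one contrast column.
# Y: n_subjects x n_voxels; X: n x p full-rank design.
glm_t_core <- function(Y, X, contrast = attr(X, "contrast") %||% 2L) {
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  tval <- beta[contrast, ] / sqrt(sigma2 * XtXi[contrast, contrast])
  # zero residual variance: no evidence either way (t = 0) when the
  # contrast estimate is also zero, undefined (NaN) otherwise
  degen <- sigma2 <= .Machine$double.eps * 1e3
  tval[degen] <- ifelse(abs(beta[contrast, degen]) <=
                          sqrt(.Machine$double.eps), 0, NaN)
  list(t = tval, df = df)
}

maps_to_matrix <- function(maps, mask) {
  idx <- which(mask$data)
  Y <- matrix(NA_real_, nrow = length(maps), ncol = length(idx))
  for (i in seq_along(maps)) {
    stopifnot_same_grid(maps[[i]], mask, "map and mask")
    Y[i, ] <- maps[[i]]$data[idx]
  }
  if (!all(is.finite(Y)))
    stop("maps contain non-finite values inside the mask", call. = FALSE)
  Y
}

#' Covariate-adjusted voxelwise two-sample t-map
#'
#' Ordinary-least-squares fit per voxel of the design built by
#' [build_design()]; the returned t-statistic is the group-contrast estimate
#' divided by its standard error, with `df = n - ncol(design)`. Voxels with
#' zero residual variance get `NaN`.
#'
#' @param maps List of per-subject `stat_map`s (row order must match the
#'   design).
#' @param design Design matrix from [build_design()].
#' @param mask `brain_mask` of analysis voxels.
#' @return A `stat_map` of kind `"tmap"` with attribute `df`.
#' @export
voxelwise_glm_t <- function(maps, design, mask) {
  if (length(maps) != nrow(design))
    stop("number of maps must match design rows", call. = FALSE)
  if (nrow(design) <= ncol(design))
    stop("need more subjects than design columns", call. = FALSE)
  Y <- maps_to_matrix(maps, mask)
  fit <- glm_t_core(Y, design)
  out <- array(NaN, grid_dims(mask))
  out[which(mask$data)] <- fit$t
  tm <- stat_map(out, mask$affine, "tmap")
  attr(tm, "df") <- fit$df
  tm
}

neighbor_offsets <- function(dims, connectivity) {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(d))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1,
                 stop("connectivity must be 6, 18, or 26", call. = FALSE))
  d <- d[keep, , drop = FALSE]
  list(steps = d, lin = d[, 1] + d[, 2] * dims[1] + d[, 3] * dims[1] * dims[2])
}

# Connected components over the suprathreshold voxel set.
# Returns an integer label per input index (1..n_clusters).
label_components <- function(idx, dims, connectivity) {
  n <- length(idx)
  labels <- integer(n)
  if (n == 0L) return(labels)
  nb <- neighbor_offsets(dims, connectivity)
  pos <- arrayInd(idx, dims)
  in_set <- integer(prod(dims))
  in_set[idx] <- seq_len(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p <- pos[v, ]
      cand <- sweep(nb$steps, 2L, p, "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
        cand[, 2] >= 1 & cand[, 2] <= dims[2] &
        cand[, 3] >= 1 & cand[, 3] <= dims[3]
      lin <- idx[v] + nb$lin[ok]
      m <- in_set[lin]
      m <- m[m != 0L]
      m <- m[labels[m] == 0L]
      if (length(m)) {
        labels[m] <- cur
        stack <- c(stack, m)
      }
    }
  }
  labels
}

max_cluster_sizes <- function(tval, idx_pool, t_crit, dims, connectivity) {
  out <- c(pos = 0L, neg = 0L)
  sup_pos <- idx_pool[which(tval > t_crit)]
  if (length(sup_pos)) {
    lab <- label_components(sup_pos, dims, connectivity)
    out["pos"] <- max(tabulate(lab))
  }
  sup_neg <- idx_pool[which(tval < -t_crit)]
  if (length(sup_neg)) {
    lab <- label_components(sup_neg, dims, connectivity)
    out["neg"] <- max(tabulate(lab))
  }
  out
}

#' Extract suprathreshold clusters from a t-map
#'
#' Thresholds the map at the two-sided cluster-forming level
#' (`|t| > qt(1 - voxel_p/2, df)`), groups surviving voxels into connected
#' components per tail, and reports each cluster's size, peak `|t|` voxel,
#' and the peak's MNI mm coordinate via the affine. Peak ties are broken by
#' the lowest linear voxel index.
#'
#' @param tmap A `stat_map` of kind `"tmap"`.
#' @param df Degrees of freedom of the t-statistics (defaults to the map's
#'   `df` attribute).
#' @param voxel_p Two-sided cluster-forming voxel threshold (default 0.001).
#' @param connectivity Neighborhood rule: 6 (faces), 18 (faces + edges,
#'   default, the SPM convention), or 26 (corners too).
#' @return A tibble with columns `cluster_id`, `tail`, `size`, `peak_t`,
#'   `peak_x`, `peak_y`, `peak_z`, plus a `voxels` list-column of linear
#'   indices. Empty tibble if nothing survives.
#' @export
extract_clusters <- function(tmap, df = attr(tmap, "df"), voxel_p = 0.001,
                             connectivity = 18) {
  stopifnot(inherits(tmap, "stat_map"))
  if (is.null(df) || df < 1) stop("`df` must be >= 1", call. = FALSE)
  dims <- grid_dims(tmap)
  t_crit <- stats::qt(1 - voxel_p / 2, df)
  res <- list()
  for (tail in c("pos", "neg")) {
    sup <- if (tail == "pos") which(tmap$data > t_crit) else
      which(tmap$data < -t_crit)
    if (!length(sup)) next
    lab <- label_components(sup, dims, connectivity)
    for (cl in seq_len(max(lab))) {
      vox <- sup[lab == cl]
      tv <- tmap$data[vox]
      peak_local <- which(abs(tv) == max(abs(tv)))
      peak <- vox[peak_local[which.min(vox[peak_local])]]
      mni <- voxel_to_world(arrayInd(peak, dims) - 1L, tmap$affine)
      res[[length(res) + 1L]] <- tibble::tibble(
        tail = tail, size = length(vox), peak_t = tmap$data[peak],
        peak_x = mni[1], peak_y = mni[2], peak_z = mni[3],
        voxels = list(vox))
    }
  }
  if (!length(res)) {
    return(tibble::tibble(cluster_id = integer(), tail = character(),
                          size = integer(), peak_t = double(),
                          peak_x = double(), peak_y = double(),
                          peak_z = double(), voxels = list()))
  }
  out <- dplyr::arrange(dplyr::bind_rows(res), dplyr::desc(.data$size))
  dplyr::mutate(out, cluster_id = dplyr::row_number(), .before = 1L)
}

#' Permutation cluster-level FWE-corrected group inference
#'
#' Fits the covariate-adjusted voxelwise GLM, forms clusters at the two-sided
#' `voxel_p` threshold, and assigns each cluster a family-wise-error-corrected
#' p-value from the permutation distribution of the maximum cluster size.
#' Permutation follows the Freedman–Lane scheme: the maps are residualized on
#' the nuisance covariates (all design columns except the group contrast),
#' the residual rows are permuted, and the full model is refit. Null maxima
#' are collected per tail; `p_fwe = (1 + #\{null >= observed size\}) /
#' (n_perm + 1)`.
#'
#' @inheritParams voxelwise_glm_t
#' @param voxel_p Two-sided cluster-forming threshold (default 0.001).
#' @param alpha_fwe Cluster-level significance level (default 0.05).
#' @param n_perm Number of permutations (default 5000, >= 100).
#' @param connectivity Cluster neighborhood rule (6, 18, 26); default 18.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An object of class `"cluster_fwe"`: a list with the observed
#'   `tmap`, the cluster tibble (`clusters`, with `p_fwe`), the per-tail null
#'   maxima (`null_max`), `df`, and the call parameters.
#' @export
permutation_cluster_fwe <- function(maps, design, mask, voxel_p = 0.001,
                                    alpha_fwe = 0.05, n_perm = 5000,
                                    connectivity = 18, seed = 1L) {
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  if (1 / (n_perm + 1) > alpha_fwe)
    warning("n_perm too small to reach alpha_fwe: minimum attainable p is ",
            signif(1 / (n_perm + 1), 3))
  if (length(maps) != nrow(design))
    stop("number of maps must match design rows", call. = FALSE)
  Y <- maps_to_matrix(maps, mask)
  dims <- grid_dims(mask)
  idx_pool <- which(mask$data)
  contrast <- attr(design, "contrast") %||% 2L
  obs <- glm_t_core(Y, design, contrast)
  t_crit <- stats::qt(1 - voxel_p / 2, obs$df)

  tmap_arr <- array(NaN, dims)
  tmap_arr[idx_pool] <- obs$t
  tmap <- stat_map(tmap_arr, mask$affine, "tmap")
  attr(tmap, "df") <- obs$df
  clusters <- extract_clusters(tmap, obs$df, voxel_p, connectivity)

  # Freedman-Lane: residualize on nuisance-only model, permute residual rows.
  Z <- design[, -contrast, drop = FALSE]
  E <- Y - Z %*% solve(crossprod(Z), crossprod(Z, Y))
  n <- nrow(Y)
  null_max <- withr::with_seed(seed, {
    t(vapply(seq_len(n_perm), function(p) {
      perm <- sample.int(n)
      tp <- glm_t_core(E[perm, , drop = FALSE], design, contrast)$t
      tp[!is.finite(tp)] <- 0
      max_cluster_sizes(tp, idx_pool, t_crit, dims, connectivity)
    }, c(pos = 0, neg = 0)))
  })

  if (nrow(clusters)) {
    clusters$p_fwe <- vapply(seq_len(nrow(clusters)), function(i) {
      nm <- null_max[, clusters$tail[i]]
      (1 + sum(nm >= clusters$size[i])) / (n_perm + 1)
    }, double(1))
  } else {
    clusters$p_fwe <- double()
  }
  structure(list(tmap = tmap, clusters = clusters, null_max = null_max,
                 df = obs$df, voxel_p = voxel_p, alpha_fwe = alpha_fwe,
                 n_perm = n_perm, connectivity = connectivity, seed = seed),
            class = "cluster_fwe")
}

#' @export
print.cluster_fwe <- function(x, ...) {
  cat(sprintf(
    "<cluster_fwe> df = %d, voxel p < %g (two-sided), %d permutations, seed %d\n",
    x$df, x$voxel_p, x$n_perm, x$seed))
  sig <- sum(x$clusters$p_fwe < x$alpha_fwe)
  cat(sprintf("  %d cluster(s), %d significant at FWE p < %g\n",
              nrow(x$clusters), sig, x$alpha_fwe))
  if (nrow(x$clusters)) print(dplyr::select(x$clusters, -"voxels"))
  invisible(x)
}

#' Convert a cluster to a binary mask
#'
#' @param result A `cluster_fwe` object or cluster tibble with a `voxels`
#'   list-column.
#' @param cluster_id Which cluster to extract.
#' @param mask A `brain_mask` providing grid and affine.
#' @return A `brain_mask` of the cluster's voxels.
#' @export
cluster_mask <- function(result, cluster_id, mask) {
  cl <- if (inherits(result, "cluster_fwe")) result$clusters else result
  row <- cl[cl$cluster_id == cluster_id, ]
  if (!nrow(row)) stop("no cluster with id ", cluster_id, call. = FALSE)
  arr <- array(FALSE, grid_dims(mask))
  arr[row$voxels[[1]]] <- TRUE
  brain_mask(arr, mask$affine)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
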