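#' Extract map values at tissue-sample locations
#'
#' Places a sphere of the given radius (MNI mm, inclusive boundary) at each
#' coordinate and averages the finite map voxels whose centers fall inside
#' it. Locations with no finite voxel in reach are dropped with a warning.
#'
#' @param tmap A `stat_map`.
#' @param coords An n x 3 matrix of MNI mm coordinates, or a tibble with
#'   columns `x`, `y`, `z` (and optionally `sample_id`).
#' @param radius Sphere radius in mm (default 3).
#' @return A `spatial_samples` tibble with columns `sample_id`, `x`, `y`,
#'   `z`, `value`; the number of dropped locations is in attribute
#'   `n_dropped`.
#' @export
extract_values_at_samples <- function(tmap, coords, radius = 3) {
  stopifnot(inherits(tmap, "stat_map"), radius > 0)
  if (is.data.frame(coords)) {
    ids <- coords$sample_id %||% sprintf("samp_%04d", seq_len(nrow(coords)))
    coords <- cbind(coords$x, coords$y, coords$z)
  } else {
    coords <- rbind2mat(coords)
    ids <- sprintf("samp_%04d", seq_len(nrow(coords)))
  }
  dims <- grid_dims(tmap)
  inv <- solve(tmap$affine)
  # conservative per-axis voxel-space half-widths covering the mm sphere
  half <- radius * sqrt(rowSums(inv[1:3, 1:3]^2))
  vals <- rep(NA_real_, nrow(coords))
  for (i in seq_len(nrow(coords))) {
    vc <- drop(inv %*% c(coords[i, ], 1))[1:3]
    lo <- pmax(ceiling(vc - half), 0)
    hi <- pmin(floor(vc + half), dims - 1L)
    if (any(lo > hi)) next
    box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    mm <- voxel_to_world(box, tmap$affine)
    d2 <- rowSums(sweep(mm, 2L, coords[i, ])^2)
    keep <- d2 <= radius^2 + 1e-9
    if (!any(keep)) next
    v <- tmap$data[box[keep, , drop = FALSE] + 1L]
    v <- v[is.finite(v)]
    if (length(v)) vals[i] <- mean(v)
  }
  dropped <- !is.finite(vals)
  if (all(dropped)) stop("no location has finite voxels in reach",
                         call. = FALSE)
  if (any(dropped))
    warning(sum(dropped), " location(s) had no finite voxel within ",
            radius, " mm and were dropped")
  out <- tibble::tibble(sample_id = ids[!dropped],
                        x = coords[!dropped, 1], y = coords[!dropped, 2],
                        z = coords[!dropped, 3], value = vals[!dropped])
  attr(out, "n_dropped") <- sum(dropped)
  class(out) <- c("spatial_samples", class(out))
  out
}

# Column-wise Pearson correlation of every column of `values` (n x G)
# against every column of `maps` (n x S). Returns G x S. Zero-variance
# columns of `values` give NaN rows. The single shared code path that
# guarantees observed and surrogate gene scores are computed identically.
gene_score_matrix <- function(values, maps) {
  n <- nrow(values)
  stopifnot(nrow(maps) == n)
  cv <- sweep(values, 2L, colMeans(values))
  cm <- sweep(maps, 2L, colMeans(maps))
  sv <- sqrt(colSums(cv^2))
  sm <- sqrt(colSums(cm^2))
  sv[sv == 0] <- NaN
  sm[sm == 0] <- NaN
  crossprod(cv, cm) / outer(sv, sm)
}

#' Gene scores: spatial correlation of expression with a statistic map
#'
#' For each gene, the Pearson correlation between its expression across the
#' tissue-sample locations and the map values at those locations. Samples
#' are aligned by `sample_id`; zero-variance genes get `NaN` and a warning.
#'
#' @param expr A `gene_expression_matrix` from [process_expression()], or a
#'   samples x genes matrix with sample ids as rownames.
#' @param samples A `spatial_samples` tibble from
#'   [extract_values_at_samples()].
#' @return A tibble with columns `gene`, `score`.
#' @export
gene_scores <- function(expr, samples) {
  values <- if (inherits(expr, "gene_expression_matrix")) expr$values else expr
  ids <- rownames(values) %||%
    (if (inherits(expr, "gene_expression_matrix")) expr$samples$sample_id else
      stop("expression matrix needs sample ids as rownames", call. = FALSE))
  m <- match(samples$sample_id, ids)
  if (anyNA(m))
    stop("samples missing from the expression matrix: ",
         paste(utils::head(samples$sample_id[is.na(m)], 3), collapse = ", "),
         call. = FALSE)
  values <- values[m, , drop = FALSE]
  sc <- gene_score_matrix(values, matrix(samples$value, ncol = 1L))[, 1]
  if (any(!is.finite(sc)))
    warning(sum(!is.finite(sc)),
            " zero-variance gene(s) scored NaN; excluded downstream")
  tibble::tibble(gene = colnames(values), score = unname(sc))
}

# Distance-decay weights. The spatial-lag model uses an exponential kernel
# with zero diagonal; the variogram-matching generator uses a Gaussian
# smoothing kernel that keeps the diagonal (self weight 1 before
# normalization) so smoothing stays local.
make_weights <- function(D, d0, generator) {
  if (generator == "spatial_lag") {
    W <- exp(-D / d0)
    diag(W) <- 0
  } else {
    W <- exp(-(D / d0)^2)
  }
  W / rowSums(W)
}

# Raw surrogate fields (before rank-remapping), n x n_surr.
surrogate_fields <- function(values, W, rho, n_surr, generator) {
  n <- length(values)
  if (generator == "spatial_lag") {
    Z <- matrix(stats::rnorm(n * n_surr), n, n_surr)
    solve(diag(n) - rho * W, Z)
  } else {
    P <- vapply(seq_len(n_surr), function(s) sample(values), double(n))
    Sz <- apply(W %*% P, 2L, scale_vec)
    Pz <- apply(P, 2L, scale_vec)
    rho * Sz + (1 - rho) * Pz
  }
}

#' Empirical variogram of a spatial sample set
#'
#' Mean half squared value difference per distance bin; by default 10
#' log-spaced bins between the 5th and 95th percentile of pairwise
#' distances.
#'
#' @param coords n x 3 coordinate matrix (mm).
#' @param values Numeric vector of length n.
#' @param n_bins Number of distance bins (default 10).
#' @param breaks Optional explicit bin breaks (overrides `n_bins`).
#' @return A tibble with columns `distance` (bin midpoint), `gamma`,
#'   `n_pairs`; bin breaks in attribute `breaks`.
#' @export
empirical_variogram <- function(coords, values, n_bins = 10, breaks = NULL) {
  D <- as.matrix(stats::dist(coords))
  ut <- upper.tri(D)
  d <- D[ut]
  if (is.null(breaks)) {
    qs <- stats::quantile(d[d > 0], c(0.05, 0.95), names = FALSE)
    breaks <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_bins + 1L))
  }
  sq <- 0.5 * (outer(values, values, "-")^2)[ut]
  bin <- cut(d, breaks, include.lowest = TRUE)
  out <- tibble::tibble(
    distance = (breaks[-1] + breaks[-length(breaks)]) / 2,
    gamma = as.vector(tapply(sq, bin, mean)),
    n_pairs = as.vector(table(bin)))
  attr(out, "breaks") <- breaks
  out
}

rank_remap <- function(y, sorted_values) {
  sorted_values[rank(y, ties.method = "first")]
}

#' Fit a surrogate-map generator to a sample map
#'
#' Calibrates the autocorrelation-preserving surrogate generator to the
#' observed map by grid search. For the default `"spatial_lag"` generator
#' the model is `y = rho * W y + noise` with distance-decay weights
#' `W_ij = exp(-d_ij / d0)` (zero diagonal, row-normalized); for
#' `"variogram_match"` it is a blend of a permuted map and its
#' Gaussian-kernel smoothing (`rho` = blend weight, `d0` = kernel scale).
#' For each candidate `(rho, d0)`, pilot surrogates are generated with the
#' chosen generator and the squared *relative* error between their mean
#' empirical variogram and the observed variogram (10 log-spaced distance
#' bins) is minimized, weighting every distance bin equally on its own
#' scale. A second, local refinement pass searches around the best coarse
#' candidate. Candidates within 50% of the minimum are resolved toward the
#' smallest `rho` (parsimony: the pilot variograms of nearby candidates
#' differ only by Monte-Carlo noise, and a map with no autocorrelation
#' should fit `rho = 0`).
#'
#' @param samples A `spatial_samples` tibble (>= 20 distinct coordinates).
#' @param rho_grid Candidate autocorrelation strengths in \[0, 0.99\].
#' @param d0_grid Candidate decay lengths (mm); default the 5th, 10th, 25th
#'   and 50th percentiles of pairwise distances.
#' @param n_pilot Pilot surrogates per candidate (default 50).
#' @param n_bins Variogram bins (default 10).
#' @param seed Integer seed for the pilot surrogates.
#' @param generator `"spatial_lag"` (default) or `"variogram_match"`; the
#'   generator used for the pilots, recorded in the fit and reused by
#'   [generate_surrogates()].
#' @return A `spatial_lag_fit`: list with `rho`, `d0`, `sse`, `generator`,
#'   the search `grid`, the observed variogram, and the sample geometry.
#' @export
fit_spatial_lag <- function(samples,
                            rho_grid = c(0, 0.3, 0.5, 0.7, 0.8, 0.9,
                                         0.95, 0.99),
                            d0_grid = NULL, n_pilot = 50, n_bins = 10,
                            seed = 1L,
                            generator = c("spatial_lag", "variogram_match")) {
  generator <- match.arg(generator)
  coords <- cbind(samples$x, samples$y, samples$z)
  values <- unname(samples$value)
  if (nrow(unique(coords)) < 20L)
    stop("need at least 20 distinct coordinates", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("map values are constant; spatial autocorrelation unidentifiable",
         call. = FALSE)
  stopifnot(all(rho_grid >= 0), all(rho_grid <= 0.99))
  D <- as.matrix(stats::dist(coords))
  if (is.null(d0_grid))
    d0_grid <- stats::quantile(D[upper.tri(D)], c(0.05, 0.1, 0.25, 0.5),
                               names = FALSE)
  obs_vg <- empirical_variogram(coords, values, n_bins)
  breaks <- attr(obs_vg, "breaks")
  sorted_vals <- sort(values)
  score_grid <- function(grid) {
    grid$sse <- vapply(seq_len(nrow(grid)), function(g) {
      W <- make_weights(D, grid$d0[g], generator)
      Y <- surrogate_fields(values, W, grid$rho[g], n_pilot, generator)
      vg <- rowMeans(vapply(seq_len(n_pilot), function(s) {
        empirical_variogram(coords, rank_remap(Y[, s], sorted_vals),
                            breaks = breaks)$gamma
      }, double(n_bins)))
      ok <- is.finite(vg) & is.finite(obs_vg$gamma) & obs_vg$gamma > 0
      sum(((vg[ok] - obs_vg$gamma[ok]) / obs_vg$gamma[ok])^2)
    }, double(1))
    grid
  }
  pick <- function(grid) {
    near <- which(grid$sse <= 1.5 * min(grid$sse))
    near[order(grid$rho[near], grid$d0[near])][1]
  }
  grid <- withr::with_seed(seed, {
    coarse <- score_grid(tidyr::expand_grid(rho = rho_grid, d0 = d0_grid))
    b <- pick(coarse)
    fine <- tidyr::expand_grid(
      rho = unique(pmin(0.99, pmax(0, coarse$rho[b] + c(-0.05, 0, 0.04)))),
      d0 = coarse$d0[b] * c(0.5, 0.65, 0.8, 1, 1.25))
    fine <- dplyr::anti_join(fine, coarse[c("rho", "d0")],
                             by = c("rho", "d0"))
    dplyr::bind_rows(coarse, score_grid(fine))
  })
  best <- pick(grid)
  structure(list(rho = grid$rho[best], d0 = grid$d0[best],
                 sse = grid$sse[best], generator = generator, grid = grid,
                 variogram = obs_vg, coords = coords, values = values,
                 seed = seed),
            class = "spatial_lag_fit")
}

#' @export
print.spatial_lag_fit <- function(x, ...) {
  cat(sprintf("<spatial_lag_fit:%s> rho = %.2f, d0 = %.1f mm (n = %d, sse = %.4g)\n",
              x$generator %||% "spatial_lag", x$rho, x$d0, nrow(x$coords),
              x$sse))
  invisible(x)
}

#' Generate spatial-autocorrelation-preserving surrogate maps
#'
#' Each surrogate is drawn from the fitted generator and rank-remapped onto
#' the original map's value multiset: the surrogate takes the original's
#' sorted values in the order of the raw field's ranks, so every
#' surrogate's value multiset equals the original's exactly. The
#' `"spatial_lag"` generator draws `y = (I - rho W)^{-1} z` with standard
#' normal `z`; with `rho = 0` the surrogates are uniformly random
#' permutations of the original values. The `"variogram_match"` generator
#' permutes the values, smooths the permutation with a Gaussian distance
#' kernel of scale `d0`, and blends smoothed and permuted components with
#' weight `rho` before remapping; it can match variograms the lag model
#' cannot represent and satisfies the same invariants.
#'
#' @param samples A `spatial_samples` tibble (the original map).
#' @param params A `spatial_lag_fit`, or a bare `list(rho =, d0 =)`.
#' @param n_surrogate Number of surrogate maps (>= 100).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param generator `"spatial_lag"` or `"variogram_match"`; defaults to the
#'   generator the fit was calibrated with.
#' @return A `surrogate_ensemble`: list with `maps` (n_surrogate x
#'   n_location), `generator`, `params`, `seed`, and the original geometry.
#' @export
generate_surrogates <- function(samples, params, n_surrogate = 1000L,
                                seed = 1L, generator = NULL) {
  if (is.null(generator)) generator <- params$generator %||% "spatial_lag"
  generator <- match.arg(generator, c("spatial_lag", "variogram_match"))
  if (n_surrogate < 100) stop("`n_surrogate` must be >= 100", call. = FALSE)
  coords <- cbind(samples$x, samples$y, samples$z)
  values <- unname(samples$value)
  rho <- params$rho
  d0 <- params$d0
  W <- make_weights(as.matrix(stats::dist(coords)), d0, generator)
  sorted_vals <- sort(values)
  maps <- withr::with_seed(seed, {
    Y <- NULL
    while (is.null(Y)) {
      Y <- tryCatch(surrogate_fields(values, W, rho, n_surrogate, generator),
                    error = function(e) NULL)
      if (is.null(Y)) {
        rho <- max(0, rho - 0.1)
        warning("surrogate operator ill-conditioned; reduced rho to ", rho)
      }
    }
    Y
  })
  maps <- apply(maps, 2L, rank_remap, sorted_values = sorted_vals)
  structure(list(maps = t(maps), generator = generator,
                 params = list(rho = rho, d0 = d0), seed = seed,
                 sample_id = samples$sample_id, coords = coords,
                 values = values),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d surrogates x %d locations (%s, rho = %.2f, d0 = %.1f, seed %d)\n",
              nrow(x$maps), ncol(x$maps), x$generator, x$params$rho,
              x$params$d0, x$seed))
  invisible(x)
}
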