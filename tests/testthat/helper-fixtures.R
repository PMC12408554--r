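# Shared fixture builders: everything is generated in code at test time.

aff_iso <- function(mm = 3, origin = NULL, dims = NULL) {
  a <- diag(c(rep(mm, 3), 1))
  if (is.null(origin) && !is.null(dims)) origin <- -(dims - 1) / 2 * mm
  if (is.null(origin)) origin <- c(0, 0, 0)
  a[1:3, 4] <- origin
  a
}

# 3D stat map from a value array (defaults to a centered 3 mm grid)
make_map <- function(values, mm = 3, kind = "tmap", affine = NULL) {
  dims <- dim(values)
  if (is.null(affine)) affine <- aff_iso(mm, dims = dims)
  stat_map(values, affine, kind)
}

full_mask <- function(dims, mm = 3, affine = NULL) {
  if (is.null(affine)) affine <- aff_iso(mm, dims = dims)
  brain_mask(array(TRUE, dims), affine)
}

# Small deterministic volume whose voxel series are supplied by `series_fun(v)`
make_volume <- function(dims, nt, tr = 2, series_fun, mm = 3) {
  arr <- array(0, c(dims, nt))
  nv <- prod(dims)
  for (v in seq_len(nv)) {
    pos <- arrayInd(v, dims)
    arr[pos[1], pos[2], pos[3], ] <- series_fun(v)
  }
  volume4d(arr, aff_iso(mm, dims = dims), tr)
}

# Hand-built toy expression bundle exercising every pipeline filter:
# 10 samples (2 donors), genes with known probe/RNA-seq relations.
toy_bundle <- function() {
  set.seed(42)
  n <- 10L
  sample_id <- sprintf("s%02d", 1:n)
  base <- list(
    gA = sin(1:n), gB = cos(1:n), gC = (1:n) / n, gD = rev(1:n) / n,
    gE = rep(c(1, 2), 5))
  # probes:
  #  pA1 faithful to gA; pA2 anti-correlated (r < 0.2) -> pA1 representative
  #  pB1/pB2 identical (tie -> pB1 by probe id)
  #  pC1 faithful but fails the intensity filter (above in 4/10)
  #  pD1 exactly orthogonal to RNA-seq gD (r = 0 < 0.2) -> gD dropped
  #  pE1 faithful but gE absent from RNA-seq -> dropped
  probe_gene <- tibble::tibble(
    probe = c("pA1", "pA2", "pB1", "pB2", "pC1", "pD1", "pE1"),
    gene = c("gA", "gA", "gB", "gB", "gC", "gD", "gE"))
  v <- rnorm(n)
  gD_c <- base$gD - mean(base$gD)
  pD1 <- v - sum(v * gD_c) / sum(gD_c^2) * gD_c   # orthogonal to gD
  probe_expr <- rbind(
    pA1 = base$gA + 0.01 * rnorm(n),
    pA2 = -base$gA,
    pB1 = base$gB,
    pB2 = base$gB,
    pC1 = base$gC,
    pD1 = pD1,
    pE1 = base$gE)
  colnames(probe_expr) <- sample_id
  above <- matrix(TRUE, nrow(probe_expr), n, dimnames = dimnames(probe_expr))
  above["pC1", ] <- c(rep(TRUE, 4), rep(FALSE, 6))
  rnaseq <- rbind(gA = base$gA, gB = base$gB, gC = base$gC, gD = base$gD)
  colnames(rnaseq) <- sample_id
  # coordinates on a 6x6x6 grid (3 mm, centered): samples 1-8 left in-atlas,
  # 9 right hemisphere, 10 left but outside the parcellation
  parc_labels <- array(0L, c(6, 6, 6))
  parc_labels[2:3, 2:5, 2:5] <- 1L   # left block (x < 0)
  parc_labels[4:5, 2:5, 2:5] <- 2L   # right block
  affine <- aff_iso(3, dims = c(6, 6, 6))
  parc <- parcellation(parc_labels, affine, region_ids = c(1L, 2L))
  vox <- rbind(
    cbind(1, 1:4, 2), cbind(2, 1:4, 3),   # 0-based, labels 1 (left)
    c(4, 2, 2),                           # right hemisphere (x > 0)
    c(1, 0, 0))                           # left, background voxel
  mm <- voxel_to_world(vox, affine)
  samples <- tibble::tibble(
    sample_id = sample_id, x = mm[, 1], y = mm[, 2], z = mm[, 3],
    donor = rep(c("D1", "D2"), each = 5), hemisphere = c(rep("left", 8),
                                                         "right", "left"))
  list(bundle = expression_bundle(probe_expr, probe_gene, above, rnaseq,
                                  samples),
       parc = parc)
}

# spatial_samples tibble from explicit coordinates and values
make_samples <- function(coords, values) {
  out <- tibble::tibble(sample_id = sprintf("s%03d", seq_len(nrow(coords))),
                        x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        value = values)
  class(out) <- c("spatial_samples", class(out))
  out
}

# scattered 3D coordinates with a smooth or white value field
random_samples <- function(n, seed, smooth_mm = NULL, extent = 60) {
  withr::with_seed(seed, {
    coords <- matrix(stats::runif(3 * n, -extent / 2, extent / 2), ncol = 3)
    if (is.null(smooth_mm)) {
      vals <- stats::rnorm(n)
    } else {
      D <- as.matrix(stats::dist(coords))
      K <- exp(-D^2 / (2 * smooth_mm^2))
      vals <- unname(drop((K / rowSums(K)) %*% stats::rnorm(n)))
      vals <- (vals - mean(vals)) / stats::sd(vals)
    }
  })
  make_samples(coords, vals)
}
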