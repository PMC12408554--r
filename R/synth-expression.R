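#' Configuration for the synthetic expression bundle generator
#'
#' Defaults mirror the emulated transcriptomic inputs: 838 tissue samples,
#' 5013 genes entering the pipeline, spatially autocorrelated expression
#' fields, a planted gene category whose members track a reference map with
#' spatial correlation `planted_r`, six donors, and decoy probes constructed
#' to fail the intensity and RNA-seq filters.
#'
#' @param n_samples Number of tissue samples to place inside the mask.
#' @param n_genes Number of genuine genes (decoy genes are added on top).
#' @param autocorr_length Gaussian kernel correlation length, mm.
#' @param planted_genes Number of planted map-tracking genes (<= `n_genes`).
#' @param planted_r Target spatial Pearson correlation between each planted
#'   gene and the reference map (|r| < 1; 0 disables the planted signal).
#' @param n_categories Number of random annotation categories (the planted
#'   category is added on top).
#' @param category_size_range Length-2 integer range of random category
#'   sizes; may straddle the 10–200 enrichment filter.
#' @param n_donors Number of synthetic donors (2–6).
#' @param seed Integer seed.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_samples = 838L, n_genes = 5013L,
                                  autocorr_length = 20, planted_genes = 40L,
                                  planted_r = 0.8, n_categories = 50L,
                                  category_size_range = c(5L, 250L),
                                  n_donors = 6L, seed = 1L) {
  stopifnot(n_samples >= 10L, n_genes >= 10L, planted_genes <= n_genes,
            planted_genes >= 1L, abs(planted_r) < 1, autocorr_length > 0,
            n_donors >= 2L, n_donors <= 6L, length(category_size_range) == 2L,
            category_size_range[1] >= 2L,
            category_size_range[1] <= category_size_range[2])
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 autocorr_length = autocorr_length,
                 planted_genes = as.integer(planted_genes),
                 planted_r = planted_r, n_categories = as.integer(n_categories),
                 category_size_range = as.integer(category_size_range),
                 n_donors = as.integer(n_donors), seed = as.integer(seed)),
            class = "expression_sim_config")
}

scale_vec <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

# Gaussian random fields at fixed locations: distance-kernel smoothing of
# white noise, kernel scale = autocorrelation length, columns standardized.
smooth_fields <- function(coords, n_fields, length_mm) {
  D <- as.matrix(stats::dist(coords))
  K <- exp(-D^2 / (2 * length_mm^2))
  K <- K / rowSums(K)
  F <- K %*% matrix(stats::rnorm(nrow(coords) * n_fields), nrow(coords))
  apply(F, 2L, scale_vec)
}

#' Generate a synthetic expression bundle
#'
#' Places `n_samples` tissue samples at distinct in-mask voxel centers
#' (hemisphere labelled by the sign of the MNI x coordinate), builds each
#' gene's expression as a spatially autocorrelated Gaussian random field,
#' mixes the planted genes with the reference map to hit the target spatial
#' correlation, and assembles a probe table with one or two probes per gene
#' plus decoy probes that fail the intensity filter (above background in only
#' 40% of samples) or the RNA-seq correlation filter. One annotation
#' category (`"C_planted"`) consists exactly of the planted genes.
#'
#' @param cfg An [expression_sim_config()].
#' @param reference A `stat_map` that is finite inside `mask` (typically the
#'   group t-map).
#' @param mask A `brain_mask` to place samples in.
#' @return An [expression_bundle()] with extra fields `annotations` (long
#'   tibble), `planted_genes`, and `planted_category`.
#' @export
gen_expression_bundle <- function(cfg, reference, mask) {
  stopifnot(inherits(cfg, "expression_sim_config"),
            inherits(reference, "stat_map"), inherits(mask, "brain_mask"))
  stopifnot_same_grid(reference, mask, "reference and mask")
  idx_pool <- which(mask$data)
  if (length(idx_pool) < cfg$n_samples)
    stop("mask too small for ", cfg$n_samples, " distinct sample coordinates",
         call. = FALSE)
  if (!all(is.finite(reference$data[idx_pool])))
    stop("reference must be finite inside the mask", call. = FALSE)

  withr::with_seed(cfg$seed, {
    n <- cfg$n_samples
    G <- cfg$n_genes
    vox <- sort(sample(idx_pool, n))
    coords <- voxel_to_world(arrayInd(vox, grid_dims(mask)) - 1L, mask$affine)
    ref_vals <- reference$data[vox]
    donors <- paste0("D", sample.int(cfg$n_donors, n, replace = TRUE))
    samples <- tibble::tibble(
      sample_id = sprintf("samp_%04d", seq_len(n)),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      donor = donors,
      hemisphere = ifelse(coords[, 1] < 0, "left", "right"))

    genes <- sprintf("GENE%05d", seq_len(G))
    planted <- genes[seq_len(cfg$planted_genes)]
    fields <- smooth_fields(coords, G, cfg$autocorr_length)
    if (cfg$planted_r != 0) {
      zref <- scale_vec(ref_vals)
      for (p in seq_len(cfg$planted_genes))
        fields[, p] <- cfg$planted_r * zref +
          sqrt(1 - cfg$planted_r^2) * fields[, p]
    }
    # gene-specific donor inconsistency: noise drawn per donor x spatial
    # block (blocks of ~autocorr_length) so it does not average away in
    # region means; low for planted genes (high DS), broad for the rest so
    # the DS filter has something to rank
    noise_sd <- stats::runif(G, 0.1, 1.2)
    noise_sd[seq_len(cfg$planted_genes)] <- stats::runif(cfg$planted_genes,
                                                         0.02, 0.1)
    block_mm <- cfg$autocorr_length
    block <- interaction(floor(coords[, 1] / block_mm),
                         floor(coords[, 2] / block_mm),
                         floor(coords[, 3] / block_mm), drop = TRUE)
    expr <- fields
    for (d in unique(donors)) {
      rows <- which(donors == d)
      Bmat <- matrix(stats::rnorm(nlevels(block) * G), nlevels(block), G)
      expr[rows, ] <- expr[rows, ] +
        Bmat[as.integer(block)[rows], , drop = FALSE] *
        rep(noise_sd, each = length(rows))
    }
    expr <- expr + matrix(stats::rnorm(n * G, sd = 0.05), n, G)
    colnames(expr) <- genes

    # probes: every gene gets a faithful probe; ~20% get a noisier second one
    probe_rows <- list(tibble::tibble(probe = sprintf("P%05d_a", seq_len(G)),
                                      gene = genes, fidelity = 0.1))
    second <- sort(sample.int(G, max(1L, round(0.2 * G))))
    probe_rows[[2]] <- tibble::tibble(probe = sprintf("P%05d_b", second),
                                      gene = genes[second], fidelity = 0.8)
    probe_gene <- dplyr::bind_rows(probe_rows)
    probe_expr <- t(expr[, probe_gene$gene, drop = FALSE]) +
      matrix(stats::rnorm(nrow(probe_gene) * n), nrow(probe_gene), n) *
      probe_gene$fidelity
    rownames(probe_expr) <- probe_gene$probe
    colnames(probe_expr) <- samples$sample_id
    above <- matrix(stats::runif(length(probe_expr)) < 0.95,
                    nrow(probe_expr), ncol(probe_expr),
                    dimnames = dimnames(probe_expr))

    # decoys: genes whose only probe fails a filter, so the gene drops out
    n_decoy <- max(3L, round(0.01 * G))
    int_genes <- sprintf("DECOY_INT%03d", seq_len(n_decoy))
    rna_genes <- sprintf("DECOY_RNA%03d", seq_len(n_decoy))
    decoy_expr <- matrix(stats::rnorm(2L * n_decoy * n), 2L * n_decoy, n)
    rownames(decoy_expr) <- c(sprintf("PDECI%03d", seq_len(n_decoy)),
                              sprintf("PDECR%03d", seq_len(n_decoy)))
    colnames(decoy_expr) <- samples$sample_id
    # intensity decoys: above background in exactly 40% of samples
    n_above <- floor(0.4 * n)
    decoy_above <- matrix(TRUE, 2L * n_decoy, n,
                          dimnames = dimnames(decoy_expr))
    for (i in seq_len(n_decoy)) {
      flags <- rep(FALSE, n)
      flags[sample.int(n, n_above)] <- TRUE
      decoy_above[i, ] <- flags
    }
    probe_gene <- dplyr::bind_rows(
      dplyr::select(probe_gene, "probe", "gene"),
      tibble::tibble(probe = rownames(decoy_expr),
                     gene = c(int_genes, rna_genes)))
    probe_expr <- rbind(probe_expr, decoy_expr)
    above <- rbind(above, decoy_above)

    # RNA-seq reference: true gene profiles plus noise; a few genuine genes
    # are left out to exercise the common-gene restriction. RNA-seq decoy
    # genes are present, but their probes are independent noise (r < 0.2).
    n_not_rna <- max(2L, round(0.002 * G))
    not_in_rna <- genes[sample((cfg$planted_genes + 1L):G, n_not_rna)]
    rna_genes_all <- c(setdiff(genes, not_in_rna), rna_genes)
    rnaseq <- rbind(t(expr[, setdiff(genes, not_in_rna), drop = FALSE]),
                    matrix(stats::rnorm(n_decoy * n), n_decoy, n))
    rnaseq <- rnaseq + matrix(stats::rnorm(length(rnaseq)), nrow(rnaseq)) * 0.3
    rownames(rnaseq) <- rna_genes_all
    colnames(rnaseq) <- samples$sample_id

    ann <- list(tibble::tibble(category_id = "C_planted", aspect = "BP",
                               gene = planted))
    for (ci in seq_len(cfg$n_categories)) {
      sz <- sample(cfg$category_size_range[1]:cfg$category_size_range[2], 1L)
      ann[[ci + 1L]] <- tibble::tibble(
        category_id = sprintf("C%04d", ci),
        aspect = sample(c("BP", "CC", "MF"), 1L),
        gene = sample(genes, min(sz, G)))
    }

    bundle <- expression_bundle(probe_expr, probe_gene, above, rnaseq, samples)
    bundle$annotations <- dplyr::bind_rows(ann)
    bundle$planted_genes <- planted
    bundle$planted_category <- "C_planted"
    bundle
  })
}

#' Generate receptor/transporter density maps with known spatial correlation
#'
#' For each requested correlation, builds a map whose region-level profile is
#' a standardized mixture `r * z(reference regions) + sqrt(1 - r^2) * noise`,
#' painted back onto the parcellation voxels with small zero-region-mean
#' jitter. The achieved region-level Pearson correlation with the reference
#' is the target up to sampling noise of order `1/sqrt(n_regions)`.
#'
#' @param reference A `stat_map` (typically the group t-map).
#' @param target_rs Numeric vector of target correlations, each |r| < 1;
#'   names become map names.
#' @param mask A `brain_mask` (same grid).
#' @param parc The `parcellation` used downstream for region averaging.
#' @param seed Integer seed.
#' @return A named list of `stat_map`s of kind `"receptor"` (`NaN` outside
#'   the parcellation).
#' @export
gen_receptor_maps <- function(reference, target_rs, mask, parc, seed = 1L) {
  stopifnot(inherits(reference, "stat_map"), inherits(mask, "brain_mask"),
            inherits(parc, "parcellation"))
  if (!length(target_rs)) stop("`target_rs` must be non-empty", call. = FALSE)
  if (any(abs(target_rs) >= 1))
    stop("|target_r| must be < 1", call. = FALSE)
  ref_regions <- parcellate(reference, parc)
  zref <- scale_vec(ref_regions$value)
  labs <- parc$labels
  map_names <- names(target_rs) %||% paste0("map_", seq_along(target_rs))
  withr::with_seed(seed, {
    out <- lapply(seq_along(target_rs), function(i) {
      r <- target_rs[i]
      y <- r * zref + sqrt(1 - r^2) * scale_vec(stats::rnorm(length(zref)))
      arr <- array(NaN, dim(labs))
      for (ri in seq_along(ref_regions$region_id)) {
        vox <- which(labs == ref_regions$region_id[ri])
        jit <- stats::rnorm(length(vox), sd = 0.02)
        arr[vox] <- y[ri] + jit - mean(jit)
      }
      stat_map(arr, parc$affine, "receptor")
    })
  })
  stats::setNames(out, map_names)
}

#' Generate a smooth synthetic reference map
#'
#' A Gaussian random field over the mask (distance-kernel smoothing of white
#' noise, standardized), useful as a stand-in for a spatially structured
#' statistic map; `NaN` outside the mask.
#'
#' @param mask A `brain_mask`.
#' @param length_mm Kernel correlation length in mm (default 10).
#' @param seed Integer seed.
#' @param kind `kind` tag of the returned map (default `"tmap"`).
#' @return A `stat_map`.
#' @export
gen_smooth_map <- function(mask, length_mm = 10, seed = 1L, kind = "tmap") {
  idx <- which(mask$data)
  coords <- voxel_to_world(arrayInd(idx, grid_dims(mask)) - 1L, mask$affine)
  withr::with_seed(seed, {
    f <- smooth_fields(coords, 1L, length_mm)[, 1]
  })
  arr <- array(NaN, grid_dims(mask))
  arr[idx] <- f
  stat_map(arr, mask$affine, kind)
}

#' Generate a synthetic gray-matter probability map
#'
#' A smooth random field squashed to (0, 1), for exercising the
#' partial-volume adjustment; `NaN` outside the mask.
#'
#' @param mask A `brain_mask`.
#' @param seed Integer seed.
#' @param length_mm Smoothing kernel scale in mm (default 15).
#' @return A `stat_map` of kind `"gm_prob"`.
#' @export
gen_gm_map <- function(mask, seed = 1L, length_mm = 15) {
  idx <- which(mask$data)
  coords <- voxel_to_world(arrayInd(idx, grid_dims(mask)) - 1L, mask$affine)
  withr::with_seed(seed, {
    f <- smooth_fields(coords, 1L, length_mm)[, 1]
  })
  arr <- array(NaN, grid_dims(mask))
  arr[idx] <- stats::plogis(f)
  stat_map(arr, mask$affine, "gm_prob")
}
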