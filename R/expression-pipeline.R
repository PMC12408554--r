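#' Expression bundle container
#'
#' Holds the raw microarray-style inputs of the transcriptomic pipeline:
#' probe x sample expression, probe-to-gene map, above-background flags, a
#' gene x sample RNA-seq reference for probe selection, and per-sample MNI
#' coordinates, donor ids, and hemisphere labels.
#'
#' @param probe_expr Numeric matrix, probes x samples, with dimnames.
#' @param probe_gene Tibble with columns `probe`, `gene` (each probe maps to
#'   exactly one gene symbol).
#' @param above_background Logical matrix, probes x samples.
#' @param rnaseq_expr Numeric matrix, genes x samples (gene subset; sample
#'   columns shared with `probe_expr`).
#' @param samples Tibble with columns `sample_id`, `x`, `y`, `z` (MNI mm),
#'   `donor`, `hemisphere` (`"left"`/`"right"`).
#' @return An `expression_bundle`.
#' @export
expression_bundle <- function(probe_expr, probe_gene, above_background,
                              rnaseq_expr, samples) {
  stopifnot(is.matrix(probe_expr), !is.null(rownames(probe_expr)),
            !is.null(colnames(probe_expr)))
  if (!all(dim(above_background) == dim(probe_expr)))
    stop("above_background must match probe_expr in shape", call. = FALSE)
  if (anyDuplicated(probe_gene$probe))
    stop("each probe must map to exactly one gene", call. = FALSE)
  if (!setequal(probe_gene$probe, rownames(probe_expr)))
    stop("probe_gene must cover exactly the probes of probe_expr",
         call. = FALSE)
  stopifnot(is.matrix(rnaseq_expr), !is.null(rownames(rnaseq_expr)))
  need <- c("sample_id", "x", "y", "z", "donor", "hemisphere")
  if (!all(need %in% names(samples)))
    stop("samples must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!identical(colnames(probe_expr), samples$sample_id))
    stop("probe_expr columns must match samples$sample_id in order",
         call. = FALSE)
  structure(list(probe_expr = probe_expr, probe_gene = tibble::as_tibble(probe_gene),
                 above_background = above_background, rnaseq_expr = rnaseq_expr,
                 samples = tibble::as_tibble(samples)),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("<expression_bundle> %d probes x %d samples, %d genes, %d RNA-seq genes, %d donors\n",
              nrow(x$probe_expr), ncol(x$probe_expr),
              length(unique(x$probe_gene$gene)), nrow(x$rnaseq_expr),
              length(unique(x$samples$donor))))
  invisible(x)
}

#' Intensity-based probe filter
#'
#' Retains a probe iff it is flagged above background noise in at least 50%
#' of samples, pooled across all donors (the boundary is inclusive: exactly
#' half passes).
#'
#' @param bundle An [expression_bundle()].
#' @return Character vector of retained probe ids.
#' @export
intensity_filter <- function(bundle) {
  stopifnot(inherits(bundle, "expression_bundle"))
  frac <- rowMeans(bundle$above_background)
  rownames(bundle$probe_expr)[frac >= 0.5]
}

#' RNA-seq-guided representative probe selection
#'
#' Genes absent from the RNA-seq reference are dropped. For each remaining
#' retained probe, the Pearson correlation between its microarray expression
#' and the gene's RNA-seq expression is computed over the shared samples;
#' probes with r < 0.2 are eliminated, and for each gene the probe with the
#' highest correlation is kept (ties broken by the lexicographically smaller
#' probe id). Genes with no surviving probe are dropped.
#'
#' @param bundle An [expression_bundle()].
#' @param retained Character vector of probes surviving
#'   [intensity_filter()].
#' @param min_r Minimum microarray/RNA-seq correlation (default 0.2).
#' @return A tibble with columns `gene`, `probe`, `r`, one row per retained
#'   gene.
#' @export
select_representative_probes <- function(bundle, retained, min_r = 0.2) {
  stopifnot(inherits(bundle, "expression_bundle"))
  pg <- bundle$probe_gene[bundle$probe_gene$probe %in% retained, ]
  pg <- pg[pg$gene %in% rownames(bundle$rnaseq_expr), ]
  if (!nrow(pg)) return(tibble::tibble(gene = character(), probe = character(),
                                       r = double()))
  shared <- intersect(colnames(bundle$probe_expr), colnames(bundle$rnaseq_expr))
  if (length(shared) < 3L)
    stop("need at least 3 shared samples between microarray and RNA-seq",
         call. = FALSE)
  pg$r <- vapply(seq_len(nrow(pg)), function(i) {
    a <- bundle$probe_expr[pg$probe[i], shared]
    b <- bundle$rnaseq_expr[pg$gene[i], shared]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, double(1))
  pg <- pg[!is.na(pg$r) & pg$r >= min_r, ]
  pg <- dplyr::arrange(pg, .data$gene, dplyr::desc(.data$r), .data$probe)
  dplyr::select(dplyr::distinct(pg, .data$gene, .keep_all = TRUE),
                "gene", "probe", "r")
}

#' Restrict samples to left-cortex atlas regions
#'
#' Keeps samples whose hemisphere label is `"left"` and whose MNI coordinate
#' falls inside a nonzero-label voxel of the parcellation (nearest-voxel
#' lookup, no search radius), recording the region each sample lands in.
#'
#' @param bundle An [expression_bundle()].
#' @param parcellation A `parcellation` in the same MNI space as the sample
#'   coordinates.
#' @return A tibble with columns `sample_id`, `region_id` for the retained
#'   samples, in bundle order.
#' @export
filter_samples <- function(bundle, parcellation) {
  stopifnot(inherits(bundle, "expression_bundle"),
            inherits(parcellation, "parcellation"))
  s <- bundle$samples
  vox <- round(world_to_voxel(cbind(s$x, s$y, s$z), parcellation$affine)) + 1L
  dims <- dim(parcellation$labels)
  inside <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
    vox[, 2] >= 1 & vox[, 2] <= dims[2] &
    vox[, 3] >= 1 & vox[, 3] <= dims[3]
  region <- rep(0L, nrow(s))
  region[inside] <- parcellation$labels[vox[inside, , drop = FALSE]]
  keep <- s$hemisphere == "left" & region > 0L
  tibble::tibble(sample_id = s$sample_id[keep], region_id = region[keep])
}

#' Scaled robust sigmoid normalization
#'
#' Outlier-robust normalization to \[0, 1\]: a sigmoid of
#' `(x - median) / (IQR / 1.35)` (IQR via linear-interpolation, type-7
#' quantiles), rescaled by its own min and max. A constant vector maps to
#' all 0.5; if the IQR is zero but the vector is not constant, the standard
#' deviation replaces the robust scale.
#'
#' @param x Numeric vector, length >= 2.
#' @return Normalized vector in \[0, 1\].
#' @export
srs_normalize <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  scale <- stats::IQR(x, type = 7) / 1.35
  if (scale == 0) scale <- stats::sd(x)
  if (!is.finite(scale) || scale == 0) return(rep(0.5, length(x)))
  # the sigmoid as a tanh: the min-max rescale is invariant to the affine
  # wrapper, and tanh's bit-exact odd symmetry pins symmetric inputs to
  # exactly 0.5 at the median
  s <- tanh((x - stats::median(x)) / (2 * scale))
  rng <- range(s)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (s - rng[1]) / (rng[2] - rng[1])
}

colwise_pearson <- function(A, B) {
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  den <- sqrt(colSums(A^2) * colSums(B^2))
  out <- colSums(A * B) / den
  out[den == 0] <- NA_real_
  out
}

#' Differential stability of regional expression
#'
#' DS of a gene is the mean, over donor pairs, of the Spearman correlation
#' between the two donors' region-mean expression vectors, computed over the
#' regions both donors sampled (pairwise complete; pairs sharing fewer than
#' `min_shared` regions are skipped). High DS marks genes whose spatial
#' expression profile is reproducible across donor brains.
#'
#' @param values Numeric matrix, samples x genes (column names are gene
#'   symbols).
#' @param region Integer region id per sample.
#' @param donor Donor id per sample.
#' @param min_shared Minimum shared regions per donor pair (default 3).
#' @return A tibble with columns `gene`, `ds`, sorted by decreasing `ds`.
#'   Genes without a valid donor pair are excluded with a warning.
#' @export
differential_stability <- function(values, region, donor, min_shared = 3L) {
  stopifnot(is.matrix(values), nrow(values) == length(region),
            nrow(values) == length(donor))
  donors <- unique(donor)
  if (length(donors) < 2L) stop("need at least 2 donors", call. = FALSE)
  # per-donor region-mean matrices (regions x genes)
  region_means <- lapply(donors, function(d) {
    rows <- donor == d
    rowsum(values[rows, , drop = FALSE], region[rows]) /
      as.vector(table(region[rows]))
  })
  names(region_means) <- donors
  G <- ncol(values)
  acc <- matrix(0, nrow = G, ncol = 0)
  for (i in seq_along(donors)[-length(donors)]) {
    for (j in (i + 1):length(donors)) {
      A <- region_means[[i]]; B <- region_means[[j]]
      shared <- intersect(rownames(A), rownames(B))
      if (length(shared) < min_shared) next
      rA <- apply(A[shared, , drop = FALSE], 2L, rank)
      rB <- apply(B[shared, , drop = FALSE], 2L, rank)
      acc <- cbind(acc, colwise_pearson(rA, rB))
    }
  }
  if (ncol(acc) == 0L)
    stop("no donor pair shares at least ", min_shared, " regions",
         call. = FALSE)
  ds <- rowMeans(acc, na.rm = TRUE)
  bad <- !is.finite(ds)
  if (any(bad)) {
    warning(sum(bad), " gene(s) had no valid donor pair and were excluded")
    ds <- ds[!bad]
  }
  out <- tibble::tibble(gene = names(ds), ds = unname(ds))
  dplyr::arrange(out, dplyr::desc(.data$ds))
}

#' @rdname differential_stability
#' @param ds_table Tibble from [differential_stability()].
#' @param fraction Fraction of top-DS genes to keep (default 0.5).
#' @export
top_ds <- function(ds_table, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- ceiling(fraction * nrow(ds_table))
  ds_table$gene[order(-ds_table$ds)][seq_len(n)]
}

#' Run the full AHBA-style expression pipeline
#'
#' Chains intensity filtering, RNA-seq-guided representative-probe
#' selection, restriction to left-hemisphere atlas samples, scaled robust
#' sigmoid normalization (within-sample across genes, then within-gene
#' across samples; applied donor-wise by default to mitigate donor effects),
#' and differential-stability gene selection (top `ds_fraction`).
#'
#' @param bundle An [expression_bundle()].
#' @param parcellation Atlas `parcellation` for sample restriction.
#' @param ds_fraction Fraction of top-DS genes retained (default 0.5).
#' @param srs_scope `"donor"` (default) applies both SRS passes within each
#'   donor before concatenation; `"pooled"` normalizes across all samples at
#'   once.
#' @param min_r Probe/RNA-seq correlation threshold (default 0.2).
#' @return A `gene_expression_matrix`: list with `values` (samples x genes,
#'   in \[0, 1\]), `samples` (tibble with coordinates, donor, region),
#'   `genes`, `ds` (the DS table), and `stages` (filter counts per stage).
#' @export
process_expression <- function(bundle, parcellation, ds_fraction = 0.5,
                               srs_scope = c("donor", "pooled"), min_r = 0.2) {
  srs_scope <- match.arg(srs_scope)
  retained <- intensity_filter(bundle)
  rep_probes <- select_representative_probes(bundle, retained, min_r)
  samp <- filter_samples(bundle, parcellation)
  if (!nrow(samp)) stop("no samples survive the atlas restriction",
                        call. = FALSE)
  if (!nrow(rep_probes)) stop("no genes survive probe selection",
                              call. = FALSE)
  # samples x genes
  values <- t(bundle$probe_expr[rep_probes$probe, samp$sample_id, drop = FALSE])
  colnames(values) <- rep_probes$gene
  meta <- dplyr::inner_join(samp, bundle$samples, by = "sample_id")

  srs_block <- function(M) {
    M <- t(apply(M, 1L, srs_normalize))      # within-sample across genes
    apply(M, 2L, srs_normalize)              # within-gene across samples
  }
  if (srs_scope == "donor") {
    for (d in unique(meta$donor)) {
      rows <- which(meta$donor == d)
      if (length(rows) >= 2L)
        values[rows, ] <- srs_block(values[rows, , drop = FALSE])
    }
  } else {
    values <- srs_block(values)
  }

  ds <- differential_stability(values, meta$region_id, meta$donor)
  keep_genes <- intersect(colnames(values), top_ds(ds, ds_fraction))
  values <- values[, keep_genes, drop = FALSE]

  stages <- tibble::tibble(
    stage = c("probes_input", "probes_intensity", "genes_representative",
              "samples_input", "samples_atlas", "genes_ds"),
    n = c(nrow(bundle$probe_expr), length(retained), nrow(rep_probes),
          nrow(bundle$samples), nrow(samp), length(keep_genes)))
  structure(list(values = values, samples = meta, genes = keep_genes,
                 ds = ds, stages = stages),
            class = "gene_expression_matrix")
}

#' @export
print.gene_expression_matrix <- function(x, ...) {
  cat(sprintf("<gene_expression_matrix> %d samples x %d genes (values in [0,1])\n",
              nrow(x$values), ncol(x$values)))
  print(x$stages)
  invisible(x)
}
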