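small_cfg <- function(n_per_group = 3L, ...) {
  sim_config(grid_dims = c(8L, 8L, 8L), n_timepoints = 24L,
             n_per_group = n_per_group, ...)
}

test_that("identical seed and config give bitwise-identical cohorts", {
  a <- gen_bold_cohort(small_cfg(seed = 9L))
  b <- gen_bold_cohort(small_cfg(seed = 9L))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$volumes[[1]]$data, b$volumes[[1]]$data)
  expect_identical(a$volumes[[6]]$data, b$volumes[[6]]$data)
  expect_identical(a$mask$data, b$mask$data)
  c <- gen_bold_cohort(small_cfg(seed = 10L))
  expect_false(identical(a$volumes[[1]]$data, c$volumes[[1]]$data))
})

test_that("the synthetic subject table passes the loader's validation", {
  coh <- gen_bold_cohort(small_cfg(seed = 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(coh$subjects, -"amplitude"), path)
  tab <- load_subject_table(path)
  expect_equal(nrow(tab), 6L)
  expect_equal(sum(tab$group == "burnout"), 3L)
  expect_error(gen_bold_cohort(sim_config(grid_dims = c(8, 8, 8),
                                          n_timepoints = 24,
                                          n_per_group = 3,
                                          effect_region = 99L)),
               "absent")
})

test_that("a planted amplitude effect lowers burnout-group fALFF in the effect region", {
  diffs <- vapply(1:5, function(s) {
    coh <- gen_bold_cohort(sim_config(grid_dims = c(10, 10, 10),
                                      n_timepoints = 80, n_per_group = 6,
                                      amplitude_ratio = 2, seed = 100L + s))
    em <- region_mask(coh$parcellation, 1L)
    means <- vapply(coh$volumes, function(v) {
      mean(falff_map(v, em)$data[em$data])
    }, double(1))
    grp <- as.character(coh$subjects$group)
    mean(means[grp == "control"]) - mean(means[grp == "burnout"])
  }, double(1))
  expect_true(all(diffs > 0))   # control fALFF higher in every replicate
})

test_that("larger amplitude ratios give larger planted group differences", {
  region_diff <- function(ratio, s) {
    coh <- gen_bold_cohort(sim_config(grid_dims = c(10, 10, 10),
                                      n_timepoints = 80, n_per_group = 8,
                                      amplitude_ratio = ratio,
                                      seed = 200L + s))
    em <- region_mask(coh$parcellation, 1L)
    means <- vapply(coh$volumes, function(v) {
      mean(falff_map(v, em)$data[em$data])
    }, double(1))
    grp <- as.character(coh$subjects$group)
    mean(means[grp == "control"]) - mean(means[grp == "burnout"])
  }
  d_small <- vapply(1:3, function(s) region_diff(1.3, s), double(1))
  d_large <- vapply(1:3, function(s) region_diff(2.5, s), double(1))
  expect_true(all(d_large > d_small))
})

test_that("clinical scores couple to the planted amplitude with the right signs", {
  coh <- gen_bold_cohort(small_cfg(n_per_group = 80L, clinical_coupling = 0.5,
                                   seed = 3L))
  burn <- coh$subjects[coh$subjects$group == "burnout", ]
  expect_lt(cor(burn$amplitude, burn$ee), -0.2)
  expect_lt(cor(burn$amplitude, burn$dp), -0.2)
  expect_gt(cor(burn$amplitude, burn$pa), 0.2)
})

test_that("synthetic expression bundles are deterministic and hit the planted correlation", {
  dims <- c(10L, 10L, 10L)
  mask <- full_mask(dims)
  set.seed(20)
  ref <- make_map(array(rnorm(prod(dims)), dims))
  cfg <- expression_sim_config(n_samples = 500L, n_genes = 60L,
                               planted_genes = 10L, planted_r = 0.8,
                               n_categories = 5L,
                               category_size_range = c(5L, 30L), seed = 4L)
  bun <- gen_expression_bundle(cfg, ref, mask)
  bun2 <- gen_expression_bundle(cfg, ref, mask)
  expect_identical(bun$probe_expr, bun2$probe_expr)
  expect_identical(bun$samples, bun2$samples)

  # construction oracle: planted gene vs reference at the sample locations
  vox <- round(world_to_voxel(cbind(bun$samples$x, bun$samples$y,
                                    bun$samples$z), mask$affine)) + 1L
  ref_vals <- ref$data[vox]
  r <- cor(bun$probe_expr[paste0("P00001_a"), ], ref_vals)
  expect_gt(r, 0.7)
  expect_lt(r, 0.9)

  # the planted category is exactly the planted genes
  pl <- bun$annotations[bun$annotations$category_id == bun$planted_category, ]
  expect_setequal(pl$gene, bun$planted_genes)

  # mask too small for the requested samples errors
  expect_error(gen_expression_bundle(
    expression_sim_config(n_samples = 5000L, n_genes = 20L,
                          planted_genes = 2L), ref, mask), "too small")
})

test_that("decoy probes fail exactly the filters they are built to fail", {
  dims <- c(10L, 10L, 10L)
  mask <- full_mask(dims)
  set.seed(21)
  ref <- make_map(array(rnorm(prod(dims)), dims))
  bun <- gen_expression_bundle(
    expression_sim_config(n_samples = 120L, n_genes = 50L,
                          planted_genes = 5L, n_categories = 3L,
                          category_size_range = c(5L, 20L), seed = 6L),
    ref, mask)
  retained <- intensity_filter(bun)
  # intensity decoys (above background in 40% of samples) are all removed
  expect_length(intersect(retained, grep("^PDECI", bun$probe_gene$probe,
                                         value = TRUE)), 0L)
  # RNA-seq decoys survive the intensity filter but not probe selection
  expect_true(all(grep("^PDECR", bun$probe_gene$probe,
                       value = TRUE) %in% retained))
  rep_probes <- select_representative_probes(bun, retained)
  expect_length(grep("^DECOY", rep_probes$gene), 0L)
  # planted genes survive both filters
  expect_true(all(bun$planted_genes %in% rep_probes$gene))
})

test_that("receptor maps achieve their target region-level correlation", {
  coh <- gen_bold_cohort(sim_config(grid_dims = c(14, 14, 14),
                                    n_timepoints = 24, n_per_group = 3,
                                    region_splits = c(5, 6, 3), seed = 2L))
  set.seed(22)
  ref <- make_map(array(rnorm(14^3), c(14, 14, 14)))
  maps <- gen_receptor_maps(ref, c(hi = 0.9, lo = -0.6), coh$mask,
                            coh$parcellation, seed = 8L)
  xr <- parcellate(ref, coh$parcellation)$value
  r_hi <- cor(xr, parcellate(maps$hi, coh$parcellation)$value)
  r_lo <- cor(xr, parcellate(maps$lo, coh$parcellation)$value)
  expect_gt(r_hi, 0.8)
  expect_lt(abs(r_lo - (-0.6)), 0.1)
  expect_error(gen_receptor_maps(ref, c(1.0), coh$mask, coh$parcellation),
               "< 1")
  expect_error(gen_receptor_maps(ref, numeric(0), coh$mask,
                                 coh$parcellation), "non-empty")
})
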