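test_that("the intensity filter uses an inclusive 50% boundary", {
  n <- 10L
  pe <- rbind(p1 = rnorm(n), p2 = rnorm(n), p3 = rnorm(n))
  colnames(pe) <- sprintf("s%02d", 1:n)
  ab <- rbind(p1 = c(rep(TRUE, 5), rep(FALSE, 5)),   # exactly 50%: retained
              p2 = c(rep(TRUE, 4), rep(FALSE, 6)),   # 40%: removed
              p3 = rep(TRUE, n))
  colnames(ab) <- colnames(pe)
  bun <- expression_bundle(
    pe, tibble::tibble(probe = c("p1", "p2", "p3"), gene = c("g1", "g2", "g3")),
    ab, matrix(rnorm(n), 1, n, dimnames = list("g1", colnames(pe))),
    tibble::tibble(sample_id = colnames(pe), x = 0, y = 0, z = 0,
                   donor = "D1", hemisphere = "left"))
  expect_setequal(intensity_filter(bun), c("p1", "p3"))
})

test_that("representative probes follow threshold, argmax and tie rules", {
  toy <- toy_bundle()
  retained <- intensity_filter(toy$bundle)
  expect_false("pC1" %in% retained)          # synthetic intensity decoy
  rep_probes <- select_representative_probes(toy$bundle, retained)
  got <- setNames(rep_probes$probe, rep_probes$gene)
  expect_equal(unname(got["gA"]), "pA1")     # anti-correlated probe dropped
  expect_equal(unname(got["gB"]), "pB1")     # tie -> lexicographically smaller
  expect_false("gC" %in% names(got))         # only probe failed intensity
  expect_false("gD" %in% names(got))         # all probes r < 0.2
  expect_false("gE" %in% names(got))         # absent from RNA-seq
})

test_that("sample restriction keeps left-hemisphere in-atlas samples only", {
  toy <- toy_bundle()
  kept <- filter_samples(toy$bundle, toy$parc)
  expect_setequal(kept$sample_id, sprintf("s%02d", 1:8))
  expect_true(all(kept$region_id == 1L))
  # s09 is right-hemisphere, s10 lands on a background voxel
  expect_false(any(c("s09", "s10") %in% kept$sample_id))
})

test_that("scaled robust sigmoid normalization has its closed-form fixed points", {
  expect_equal(srs_normalize(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(srs_normalize(rep(7, 5)), rep(0.5, 5))
  set.seed(50)
  x <- rnorm(40, sd = 4)
  s <- srs_normalize(x)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(rank(s), rank(x))                     # order preserved
  expect_equal(srs_normalize(2.5 * x + 7), s, tolerance = 1e-12)  # affine invariant
})

test_that("differential stability is 1 for rank-identical donors and ~0 under independence", {
  # two donors sampling one location per region, donor 2 a monotone
  # transform of donor 1: rank invariance makes DS exactly 1
  set.seed(53)
  regions <- 1:8
  donors <- rep(c("D1", "D2"), each = 8)
  base <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(NULL, paste0("g", 1:5)))
  vals <- rbind(base, exp(base))
  ds <- differential_stability(vals, c(regions, regions), donors)
  expect_equal(ds$ds, rep(1, 5))
  # identical region means likewise
  ds_id <- differential_stability(rbind(base, base), c(regions, regions),
                                  donors)
  expect_equal(ds_id$ds, rep(1, 5))
  # independent donors, 50 regions: mean DS near 0
  set.seed(51)
  nr <- 50L
  vals2 <- matrix(rnorm(2 * nr * 300), 2 * nr, 300,
                  dimnames = list(NULL, sprintf("g%03d", 1:300)))
  ds2 <- differential_stability(vals2, rep(1:nr, 2),
                                rep(c("D1", "D2"), each = nr))
  expect_lt(abs(mean(ds2$ds)), 0.05)
  # top_ds keeps the highest-DS half
  top <- top_ds(ds2, 0.5)
  expect_length(top, 150L)
  expect_gte(min(ds2$ds[ds2$gene %in% top]),
             max(ds2$ds[!ds2$gene %in% top]))
  expect_error(differential_stability(vals2[1:50, , drop = FALSE],
                                      rep(1:nr, length.out = 50),
                                      rep("D1", 50)), "2 donors")
})

test_that("the full pipeline keeps planted genes, drops decoys, and bounds values", {
  coh <- gen_bold_cohort(sim_config(grid_dims = c(10, 10, 10),
                                    n_timepoints = 24, n_per_group = 3,
                                    region_splits = c(4, 4, 4), seed = 2L))
  # spatially smooth reference (as a real t-map is), so planted genes have
  # donor-consistent regional structure
  set.seed(52)
  idx <- which(coh$mask$data)
  mm <- voxel_to_world(arrayInd(idx, c(10, 10, 10)) - 1L, coh$mask$affine)
  K <- exp(-as.matrix(dist(mm))^2 / (2 * 8^2))
  ref_arr <- array(NaN, c(10, 10, 10))
  ref_arr[idx] <- (K / rowSums(K)) %*% rnorm(length(idx))
  ref <- stat_map(ref_arr, coh$mask$affine, "tmap")
  bun <- gen_expression_bundle(
    expression_sim_config(n_samples = 300L, n_genes = 80L, planted_genes = 8L,
                          planted_r = 0.7, n_categories = 4L,
                          category_size_range = c(5L, 30L), n_donors = 3L,
                          seed = 7L), ref, coh$mask)
  gem <- process_expression(bun, coh$parcellation)
  expect_true(all(gem$values >= 0 & gem$values <= 1))
  expect_false(any(is.na(gem$values)))
  # planted genes survive every stage; decoy genes never appear
  expect_true(all(bun$planted_genes %in% gem$genes))
  expect_length(grep("^DECOY", gem$genes), 0L)
  # end-to-end containment: survivors passed every upstream filter
  retained <- intensity_filter(bun)
  rep_probes <- select_representative_probes(bun, retained)
  expect_true(all(gem$genes %in% rep_probes$gene))
  expect_true(all(rep_probes$probe[match(gem$genes, rep_probes$gene)] %in%
                    retained))
  expect_true(all(gem$samples$sample_id %in%
                    filter_samples(bun, coh$parcellation)$sample_id))
  # DS selection kept the top half
  expect_equal(length(gem$genes),
               length(intersect(top_ds(gem$ds, 0.5), rep_probes$gene)))
  # stage counts are monotone where they must be
  st <- setNames(gem$stages$n, gem$stages$stage)
  expect_lte(st["probes_intensity"], st["probes_input"])
  expect_lte(st["genes_ds"], st["genes_representative"])
})
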