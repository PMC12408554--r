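# build a list of stat maps from an n_subj x n_vox matrix
maps_from_matrix <- function(Y, dims, mm = 3) {
  lapply(seq_len(nrow(Y)), function(i) {
    make_map(array(Y[i, ], dims), mm = mm)
  })
}

toy_subjects <- function(n_per_group, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(2 * n_per_group)),
    group = factor(rep(c("burnout", "control"), each = n_per_group),
                   levels = c("burnout", "control")),
    age = round(runif(2 * n_per_group, 22, 40)),
    education = round(runif(2 * n_per_group, 12, 20)),
    tiv = rnorm(2 * n_per_group, 1420, 100),
    bai = runif(2 * n_per_group, 10, 40),
    bdi = runif(2 * n_per_group, 0, 20),
    ee = runif(2 * n_per_group, 0, 50), dp = runif(2 * n_per_group, 0, 25),
    pa = runif(2 * n_per_group, 5, 45)))
}

test_that("identical maps across subjects give t = 0 everywhere", {
  dims <- c(3L, 3L, 3L)
  base <- rnorm(27)
  Y <- matrix(rep(base, each = 10), nrow = 10)
  subj <- toy_subjects(5)
  tm <- voxelwise_glm_t(maps_from_matrix(Y, dims), build_design(subj),
                        full_mask(dims))
  expect_true(all(tm$data == 0))
})

test_that("an intercept+group design reproduces the pooled-variance two-sample t", {
  dims <- c(4L, 4L, 2L)
  set.seed(30)
  Y <- matrix(rnorm(12 * 32), nrow = 12)
  subj <- toy_subjects(6)
  X <- build_design(subj, covariates = character(0))
  tm <- voxelwise_glm_t(maps_from_matrix(Y, dims), X, full_mask(dims))
  g <- as.character(subj$group) == "burnout"
  for (v in seq_len(32)) {
    a <- Y[g, v]; b <- Y[!g, v]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    t_cf <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
    expect_equal(tm$data[v], t_cf, tolerance = 1e-10)
  }
  expect_equal(attr(tm, "df"), 10L)
})

test_that("the full covariate design equals a per-voxel regression loop oracle", {
  dims <- c(3L, 3L, 3L)
  set.seed(31)
  Y <- matrix(rnorm(16 * 27), nrow = 16)
  subj <- toy_subjects(8)
  X <- build_design(subj)
  tm <- voxelwise_glm_t(maps_from_matrix(Y, dims), X, full_mask(dims))
  for (v in seq_len(27)) {
    fit <- summary(lm(Y[, v] ~ 0 + X))$coefficients
    expect_equal(tm$data[v], fit["Xgroup", "t value"], tolerance = 1e-8)
  }
  expect_equal(attr(tm, "df"), 16L - 7L)
})

test_that("swapping the group labels negates the t-map exactly", {
  dims <- c(3L, 3L, 3L)
  set.seed(32)
  Y <- matrix(rnorm(14 * 27), nrow = 14)
  subj <- toy_subjects(7)
  swapped <- dplyr::mutate(subj, group = factor(
    ifelse(group == "burnout", "control", "burnout"),
    levels = c("burnout", "control")))
  mask <- full_mask(dims)
  t1 <- voxelwise_glm_t(maps_from_matrix(Y, dims), build_design(subj), mask)
  t2 <- voxelwise_glm_t(maps_from_matrix(Y, dims), build_design(swapped), mask)
  expect_equal(t1$data, -t2$data, tolerance = 1e-12)
})

test_that("cluster connectivity semantics distinguish 6, 18 and 26 neighborhoods", {
  dims <- c(8L, 8L, 8L)
  tm <- array(0, dims)
  # blob A: 4 voxels; blob B: 3 voxels; they share only the corner (4,4,4)-(5,5,5)
  tm[2:4, 4, 4] <- 6; tm[4, 3, 4] <- 6
  tm[5, 5, 5] <- 6; tm[6, 5, 5] <- 6; tm[6, 6, 5] <- 6
  map <- make_map(tm)
  cl6 <- extract_clusters(map, df = 20, connectivity = 6)
  cl26 <- extract_clusters(map, df = 20, connectivity = 26)
  expect_equal(sort(cl6$size), c(3L, 4L))
  expect_equal(cl26$size, 7L)
  # edge-sharing blobs merge at 18 but not at 6
  tm2 <- array(0, dims)
  tm2[2, 2, 2] <- 6
  tm2[3, 3, 2] <- 6  # shares an edge with (2,2,2)
  map2 <- make_map(tm2)
  expect_equal(nrow(extract_clusters(map2, df = 20, connectivity = 6)), 2L)
  expect_equal(nrow(extract_clusters(map2, df = 20, connectivity = 18)), 1L)
})

test_that("cluster reports are complete, signed, and deterministic in ties", {
  dims <- c(8L, 8L, 8L)
  set.seed(33)
  tm <- array(rnorm(prod(dims), sd = 0.5), dims)
  tm[2:3, 2:3, 2] <- 5.5       # positive blob
  tm[6:7, 6, 6] <- -6          # negative blob, tied peaks
  map <- make_map(tm)
  cl <- extract_clusters(map, df = 30, voxel_p = 0.001)
  t_crit <- qt(1 - 0.001 / 2, 30)
  # sizes per tail sum to the suprathreshold voxel counts
  expect_equal(sum(cl$size[cl$tail == "pos"]), sum(tm > t_crit))
  expect_equal(sum(cl$size[cl$tail == "neg"]), sum(tm < -t_crit))
  # tied |t| peak resolves to the lowest linear voxel index
  neg <- cl[cl$tail == "neg", ]
  peak_vox <- arrayInd(which(tm == -6)[1], dims) - 1L
  expect_equal(c(neg$peak_x, neg$peak_y, neg$peak_z),
               as.vector(voxel_to_world(peak_vox, map$affine)))
  # nothing survives an impossible threshold
  expect_equal(nrow(extract_clusters(make_map(array(0.1, dims)), df = 30)),
               0L)
})

test_that("permutation FWE is deterministic, floored at 1/(n_perm+1), and warns sensibly", {
  dims <- c(6L, 6L, 6L)
  set.seed(34)
  n <- 12L
  Y <- matrix(rnorm(n * prod(dims)), nrow = n)
  # plant a big group effect in 8 voxels
  subj <- toy_subjects(6)
  g <- as.character(subj$group) == "burnout"
  Y[g, 1:8] <- Y[g, 1:8] - 8
  maps <- maps_from_matrix(Y, dims)
  X <- build_design(subj, covariates = c("age", "tiv"))
  mask <- full_mask(dims)
  r1 <- permutation_cluster_fwe(maps, X, mask, n_perm = 199, seed = 5)
  r2 <- permutation_cluster_fwe(maps, X, mask, n_perm = 199, seed = 5)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$null_max, r2$null_max)
  top <- r1$clusters[1, ]
  expect_equal(top$tail, "neg")
  # observed size exceeds every permuted maximum -> estimator floor
  expect_true(all(r1$null_max[, "neg"] < top$size))
  expect_equal(top$p_fwe, 1 / 200)
  expect_error(permutation_cluster_fwe(maps, X, mask, n_perm = 50),
               ">= 100")
  expect_warning(permutation_cluster_fwe(maps, X, mask, n_perm = 100,
                                         alpha_fwe = 0.001, seed = 1),
                 "minimum attainable")
})
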