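test_that("the amplitude spectrum obeys Fourier identities and Parseval", {
  tr <- 2
  nt <- 240L
  tt <- (0:(nt - 1)) * tr
  # pure cosine at bin k: amplitude concentrated there, ~0 elsewhere
  k <- 24L  # 0.05 Hz
  x <- cos(2 * pi * k / (nt * tr) * tt)
  sp <- sqrt_power_spectrum(x, tr)
  expect_equal(sp$frequency[k + 1], 0.05)
  expect_gt(sp$amplitude[k + 1], 0.9 * max(sp$amplitude))
  expect_lt(max(sp$amplitude[-(k + 1)]), 1e-10 * sp$amplitude[k + 1])
  # constant series: all non-DC amplitudes zero
  spc <- sqrt_power_spectrum(rep(3, nt), tr)
  expect_lt(max(spc$amplitude[-1]), 1e-12)
  expect_equal(spc$amplitude[1], sqrt(nt) * 3)
  # Parseval: sum of squared amplitudes equals total signal power
  for (n in c(64L, 101L)) {   # even and odd lengths
    y <- rnorm(n)
    spy <- sqrt_power_spectrum(y, tr)
    expect_equal(sum(spy$amplitude^2), sum(y^2), tolerance = 1e-8)
  }
  expect_error(sqrt_power_spectrum(c(1, NA, rep(0, 10)), tr), "finite")
})

test_that("fALFF spectral identities hold", {
  tr <- 2
  nt <- 240L
  tt <- (0:(nt - 1)) * tr
  sine <- sin(2 * pi * 0.05 * tt)
  # all non-DC power inside the ALFF band: fALFF is exactly 1
  expect_equal(compute_falff(sine, tr, detrend = FALSE), 1.0)
  # trend removal leaks a little amplitude into the sub-band bins
  expect_gt(compute_falff(sine, tr), 0.95)
  # degenerate constant series: 0 with a warning
  expect_warning(f0 <- compute_falff(rep(5, nt), tr), "zero power")
  expect_equal(f0, 0)
  # scale invariance and range
  set.seed(10)
  x <- rnorm(nt)
  f <- compute_falff(x, tr)
  expect_equal(compute_falff(17.3 * x, tr), f, tolerance = 1e-12)
  expect_true(f >= 0 && f <= 1)
})

test_that("fALFF maps match a voxel-by-voxel loop oracle", {
  dims <- c(4L, 4L, 4L)
  nt <- 60L
  set.seed(11)
  vol <- make_volume(dims, nt, tr = 2,
                     series_fun = function(v) rnorm(nt) +
                       0.5 * sin(2 * pi * 0.05 * (0:(nt - 1)) * 2 + v))
  mask <- full_mask(dims)
  map <- falff_map(vol, mask)
  oracle <- array(NA_real_, dims)
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    oracle[i, j, k] <- compute_falff(vol$data[i, j, k, ], 2)
  }
  expect_equal(map$data, oracle, tolerance = 1e-12)
  # homogeneous volume gives a constant map; out-of-mask voxels are NaN
  series <- rnorm(nt)
  hom <- make_volume(dims, nt, tr = 2, series_fun = function(v) series)
  part <- brain_mask(array(rep(c(TRUE, FALSE), 32), dims), vol$affine)
  hm <- falff_map(hom, part)
  expect_equal(diff(range(hm$data[part$data])), 0, tolerance = 1e-12)
  expect_true(all(is.nan(hm$data[!part$data])))
})

test_that("Fisher z-standardization matches atanh and is odd and monotone", {
  expect_equal(fisher_z_standardize(0), 0)
  expect_equal(fisher_z_standardize(0.5), 0.54930614, tolerance = 1e-8)
  expect_equal(fisher_z_standardize(0.9), 1.47221949, tolerance = 1e-8)
  v <- seq(-0.95, 0.95, by = 0.05)
  z <- fisher_z_standardize(v)
  expect_true(all(diff(z) > 0))
  expect_equal(fisher_z_standardize(-v), -z)
  # clipping keeps values >= 1 finite
  expect_equal(fisher_z_standardize(1), atanh(1 - 1e-7))
  expect_equal(fisher_z_standardize(1.2), atanh(1 - 1e-7))
  # stat_map method preserves NaN
  m <- make_map(array(c(0.5, NaN, rep(0, 6)), c(2, 2, 2)))
  zm <- fisher_z_standardize(m)
  expect_true(is.nan(zm$data[2]))
  expect_equal(zm$data[1], atanh(0.5))
})

test_that("seed FC maps equal a per-voxel Pearson loop oracle", {
  dims <- c(4L, 4L, 4L)
  nt <- 60L
  set.seed(12)
  vol <- make_volume(dims, nt, tr = 2, series_fun = function(v) rnorm(nt))
  mask <- full_mask(dims)
  seed_arr <- array(FALSE, dims)
  seed_arr[1:2, 1, 1] <- TRUE
  seed <- brain_mask(seed_arr, vol$affine)
  fc <- seed_fc_map(vol, seed, mask)
  s <- rowMeans(cbind(vol$data[1, 1, 1, ], vol$data[2, 1, 1, ]))
  for (v in c(1L, 17L, 33L, 64L)) {
    pos <- arrayInd(v, dims)
    r <- cor(s, vol$data[pos[1], pos[2], pos[3], ])
    expect_equal(fc$data[v], atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)),
                 tolerance = 1e-12)
  }
})

test_that("seed FC handles self, negated, and degenerate series", {
  dims <- c(3L, 3L, 3L)
  nt <- 40L
  set.seed(13)
  s <- rnorm(nt)
  vol <- make_volume(dims, nt, tr = 2, series_fun = function(v) {
    if (v == 1) s else if (v == 2) -s else if (v == 3) rep(1, nt) else rnorm(nt)
  })
  mask <- full_mask(dims)
  seed_arr <- array(FALSE, dims)
  seed_arr[1, 1, 1] <- TRUE
  fc <- seed_fc_map(vol, brain_mask(seed_arr, vol$affine), mask)
  zmax <- atanh(1 - 1e-7)
  expect_equal(fc$data[1], zmax)    # identical to seed mean
  expect_equal(fc$data[2], -zmax)   # negated
  expect_true(is.nan(fc$data[3]))   # constant voxel
  # zero-variance seed mean errors
  cseed <- array(FALSE, dims)
  cseed[3, 1, 1] <- TRUE
  expect_error(seed_fc_map(vol, brain_mask(cseed, vol$affine), mask),
               "zero variance")
  # seed outside the mask errors
  m2 <- mask
  m2$data[1, 1, 1] <- FALSE
  expect_error(seed_fc_map(vol, brain_mask(seed_arr, vol$affine),
                           brain_mask(m2$data, vol$affine)), "subset")
})
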