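#' Configuration for the synthetic BOLD cohort generator
#'
#' Defaults mirror the emulated study: two groups of 51 subjects, 240
#' timepoints at TR = 2 s, a planted reduction of band-limited amplitude in
#' one region of the burnout group (controls' amplitude is
#' `amplitude_ratio` times larger there), AR(1) voxel noise, and Maslach
#' subscale scores coupled to the planted subject amplitude (EE and DP
#' negatively, PA positively) through a Gaussian copula.
#'
#' @param grid_dims Integer 3-vector of grid dimensions (3 mm voxels).
#' @param n_timepoints Number of timepoints (>= 8).
#' @param tr Repetition time, seconds.
#' @param n_per_group Subjects per group (>= 3).
#' @param effect_region Region id carrying the planted group effect.
#' @param amplitude_ratio Multiplicative band-limited amplitude factor for
#'   controls relative to burnout inside `effect_region`; > 1 plants the
#'   observed direction (lower amplitude in burnout), 1 is the global null.
#' @param ar1_rho Lag-1 autocorrelation of the voxel noise, in \[0, 1).
#' @param clinical_coupling Target |Pearson correlation| between the planted
#'   per-subject amplitude and EE (negative), DP (negative), PA (positive).
#' @param region_splits Blocks per axis for the synthetic parcellation
#'   (length 1 or 3); the grid interior is split into
#'   `prod(region_splits)` box-shaped regions. Default `c(2, 2, 2)` (8
#'   octants); use e.g. `c(5, 6, 3)` for an AAL-90-like region count.
#' @param seed Integer seed; identical config + seed gives bitwise-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_dims = c(16L, 16L, 16L), n_timepoints = 240L,
                       tr = 2, n_per_group = 51L, effect_region = 1L,
                       amplitude_ratio = 1.5, ar1_rho = 0.3,
                       clinical_coupling = 0.3,
                       region_splits = c(2L, 2L, 2L), seed = 1L) {
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 6L),
            n_timepoints >= 8L, tr > 0, n_per_group >= 3L,
            amplitude_ratio > 0, ar1_rho >= 0, ar1_rho < 1,
            abs(clinical_coupling) < 1)
  if (length(region_splits) == 1L) region_splits <- rep(region_splits, 3L)
  stopifnot(length(region_splits) == 3L, all(region_splits >= 1L),
            all(region_splits <= grid_dims - 2L))
  structure(list(grid_dims = as.integer(grid_dims),
                 n_timepoints = as.integer(n_timepoints), tr = tr,
                 n_per_group = as.integer(n_per_group),
                 effect_region = as.integer(effect_region),
                 amplitude_ratio = amplitude_ratio, ar1_rho = ar1_rho,
                 clinical_coupling = clinical_coupling,
                 region_splits = as.integer(region_splits),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# 3 mm isotropic affine centered on the grid (x < 0 is the left hemisphere).
centered_affine <- function(dims, voxel_mm = 3) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -(dims - 1) / 2 * voxel_mm
  aff
}

# Interior of the grid (1-voxel border excluded) split into box regions,
# `splits` blocks per axis.
block_parcellation <- function(dims, affine, splits = c(2L, 2L, 2L)) {
  labels <- array(0L, dims)
  block <- function(ax) {
    inner <- dims[ax] - 2L
    pmin(splits[ax], 1L + ((seq_len(inner) - 1L) * splits[ax]) %/% inner)
  }
  bi <- block(1); bj <- block(2); bk <- block(3)
  for (i in seq_len(dims[1] - 2L)) for (j in seq_len(dims[2] - 2L))
    for (k in seq_len(dims[3] - 2L)) {
      labels[i + 1L, j + 1L, k + 1L] <-
        bi[i] + (bj[j] - 1L) * splits[1] + (bk[k] - 1L) * splits[1] * splits[2]
    }
  n <- prod(splits)
  parcellation(labels, affine, region_ids = seq_len(n),
               names = sprintf("block_%02d", seq_len(n)))
}

truncate_score <- function(x) pmax(0, round(x, 1))

#' Generate a synthetic resting-state cohort
#'
#' Produces per-subject 4D volumes, a brain mask, a block parcellation of
#' the grid interior, and a subject table with the structure the group
#' analysis assumes. Each
#' in-mask voxel's series is AR(1) Gaussian noise (unit marginal SD) plus a
#' shared band-limited oscillation — a sum of 5 unit-power sinusoids with
#' random phases at frequencies uniform in 0.02–0.08 Hz — whose amplitude
#' inside `effect_region` is scaled by group (`controls x amplitude_ratio`)
#' and by a per-subject factor. EE/DP/PA are drawn from group-realistic
#' marginals with latent-normal coupling to that subject factor, so that
#' corr(amplitude, EE) is approximately `-|clinical_coupling|` and
#' corr(amplitude, PA) approximately `+|clinical_coupling|`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `volumes` (list of `volume4d`), `mask`
#'   (`brain_mask` over the grid interior), `parcellation` (box regions per
#'   `region_splits`), and `subjects` (tibble, including the ground-truth
#'   planted `amplitude`).
#' @export
gen_bold_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dims <- cfg$grid_dims
  affine <- centered_affine(dims)
  parc <- block_parcellation(dims, affine, cfg$region_splits)
  if (!cfg$effect_region %in% parc$region_ids)
    stop("effect_region ", cfg$effect_region, " absent from parcellation",
         call. = FALSE)
  mask_arr <- parc$labels > 0L
  mask <- brain_mask(mask_arr, affine)
  idx <- which(mask_arr)
  nvox <- length(idx)
  nvox_total <- prod(dims)
  in_effect <- parc$labels[idx] == cfg$effect_region
  nt <- cfg$n_timepoints
  n <- 2L * cfg$n_per_group
  tt <- (seq_len(nt) - 1L) * cfg$tr

  withr::with_seed(cfg$seed, {
    group <- rep(c("burnout", "control"), each = cfg$n_per_group)
    u <- stats::rnorm(n)                    # latent amplitude deviate
    subj_factor <- pmax(0.2, 1 + 0.15 * u)
    group_scale <- ifelse(group == "control", cfg$amplitude_ratio, 1)
    amplitude <- subj_factor * group_scale

    cc <- abs(cfg$clinical_coupling)
    couple <- function(sign) sign * cc * u + sqrt(1 - cc^2) * stats::rnorm(n)
    burn <- group == "burnout"
    mu_sd <- function(mu_b, sd_b, mu_c, sd_c) {
      list(mu = ifelse(burn, mu_b, mu_c), sd = ifelse(burn, sd_b, sd_c))
    }
    ee_m <- mu_sd(23, 12, 13, 6); dp_m <- mu_sd(12, 6, 3, 3)
    pa_m <- mu_sd(24.5, 9.7, 38, 7)
    subjects <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = factor(group, levels = c("burnout", "control")),
      age = pmin(40, pmax(20, round(stats::rnorm(n, 32, 5)))),
      education = pmin(22, pmax(12, round(stats::rnorm(n, 16, 1)))),
      tiv = round(stats::rnorm(n, 1420, 130), 1),
      bai = truncate_score(ifelse(burn, 29, 24) + stats::rnorm(n, 0, ifelse(burn, 6, 3))),
      bdi = truncate_score(ifelse(burn, 9, 4) + stats::rnorm(n, 0, ifelse(burn, 6, 3))),
      ee = truncate_score(ee_m$mu + ee_m$sd * couple(-1)),
      dp = truncate_score(dp_m$mu + dp_m$sd * couple(-1)),
      pa = truncate_score(pa_m$mu + pa_m$sd * couple(+1)),
      amplitude = amplitude)

    sd_innov <- sqrt(1 - cfg$ar1_rho^2)
    volumes <- lapply(seq_len(n), function(s) {
      freqs <- stats::runif(5, 0.02, 0.08)
      phases <- stats::runif(5, 0, 2 * pi)
      sig <- sqrt(2 / 5) * rowSums(sin(outer(tt, 2 * pi * freqs) +
                                         rep(phases, each = nt)))
      noise <- matrix(stats::rnorm(nt * nvox, sd = sd_innov), nt, nvox)
      noise[1, ] <- stats::rnorm(nvox)      # stationary start
      for (t in 2:nt)
        noise[t, ] <- cfg$ar1_rho * noise[t - 1L, ] + noise[t, ]
      amp_vox <- rep(1, nvox)
      amp_vox[in_effect] <- amplitude[s]
      M <- noise + outer(sig, amp_vox)
      arr <- array(0, c(dims, nt))
      arr[rep(idx, nt) + rep((0:(nt - 1L)) * nvox_total, each = nvox)] <-
        as.vector(t(M))
      volume4d(arr, affine, cfg$tr)
    })
  })
  list(volumes = volumes, mask = mask, parcellation = parc,
       subjects = subjects)
}

#' Region mask from a parcellation
#'
#' @param parc A `parcellation`.
#' @param region_id Region to extract.
#' @return A `brain_mask` of the region's voxels.
#' @export
region_mask <- function(parc, region_id) {
  stopifnot(inherits(parc, "parcellation"))
  if (!region_id %in% parc$region_ids)
    stop("region ", region_id, " not in parcellation", call. = FALSE)
  brain_mask(parc$labels == region_id, parc$affine)
}
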