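#' Frequency band specification
#'
#' The low-frequency band whose amplitude defines ALFF (default 0.01–0.1 Hz)
#' nested inside the total analyzed range (default 0.01–0.25 Hz) that
#' normalizes it to fALFF. Bands are closed intervals in Hz; a spectral bin at
#' frequency f is in-band iff `low <= f <= high`.
#'
#' @param low,high ALFF band edges in Hz.
#' @param total_low,total_high Total analyzed range in Hz.
#' @return A `band_spec` list.
#' @export
band_spec <- function(low = 0.01, high = 0.1,
                      total_low = 0.01, total_high = 0.25) {
  if (!(0 < low && low < high && high <= total_high && total_low <= low))
    stop("invalid band: need 0 < low < high <= total_high and total_low <= low",
         call. = FALSE)
  structure(list(low = low, high = high,
                 total_low = total_low, total_high = total_high),
            class = "band_spec")
}

validate_band <- function(band, tr) {
  nyquist <- 1 / (2 * tr)
  if (band$high > nyquist + 1e-12)
    stop(sprintf("band high (%g Hz) exceeds Nyquist (%g Hz) for TR = %g s",
                 band$high, nyquist, tr), call. = FALSE)
  invisible(TRUE)
}

#' Remove a linear trend from a time series
#'
#' Minimal preprocessing utility: ordinary least-squares removal of intercept
#' and linear slope. Operates column-wise when given a matrix.
#'
#' @param x Numeric vector or matrix (time in rows).
#' @return Detrended vector or matrix.
#' @export
detrend_linear <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  X <- cbind(1, seq_len(n) - (n + 1) / 2)
  out <- x - X %*% solve(crossprod(X), crossprod(X, x))
  if (vec) drop(out) else out
}

#' Regress nuisance signals out of a time series matrix
#'
#' Minimal preprocessing utility: returns the residuals of each column of `x`
#' after OLS regression on `confounds` (an intercept is always included).
#'
#' @param x Numeric matrix, time in rows.
#' @param confounds Numeric matrix of nuisance regressors, time in rows.
#' @return Residual matrix with the dimensions of `x`.
#' @export
nuisance_regress <- function(x, confounds) {
  Z <- cbind(1, as.matrix(confounds))
  if (nrow(Z) != nrow(x)) stop("confounds must match x in rows", call. = FALSE)
  x - Z %*% solve(crossprod(Z), crossprod(Z, x))
}

# One-sided amplitude spectrum with Parseval-consistent scaling:
# sum(amplitude^2) == sum(x^2). Returns K+1 bins at k/(T*tr) Hz, k = 0..K.
one_sided_amplitude <- function(x, tr) {
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  K <- n %/% 2L
  k <- 0:K
  w <- rep(2, K + 1L)
  w[1] <- 1
  if (n %% 2L == 0L) w[K + 1L] <- 1
  if (is.null(dim(x))) {
    amp <- sqrt(w) * Mod(stats::fft(x))[k + 1L] / sqrt(n)
  } else {
    amp <- sqrt(w) * Mod(stats::mvfft(x))[k + 1L, , drop = FALSE] / sqrt(n)
  }
  list(frequency = k / (n * tr), amplitude = amp)
}

#' Square-root power spectrum of a BOLD time series
#'
#' Discrete-Fourier one-sided amplitude spectrum: the square root of the power
#' at each frequency bin k/(T·tr) Hz, k = 0..floor(T/2). Amplitudes are scaled
#' so that the sum of their squares equals the total signal power
#' `sum(ts^2)` (Parseval). The DC bin is reported but falls outside every
#' analysis band (bands start at 0.01 Hz or above).
#'
#' @param ts Numeric time series, length >= 8.
#' @param tr Repetition time in seconds.
#' @return A tibble with columns `frequency` (Hz) and `amplitude`.
#' @export
sqrt_power_spectrum <- function(ts, tr) {
  if (length(ts) < 8L) stop("need at least 8 timepoints", call. = FALSE)
  if (!all(is.finite(ts))) stop("time series contains non-finite values",
                                call. = FALSE)
  if (!is.finite(tr) || tr <= 0) stop("`tr` must be positive", call. = FALSE)
  sp <- one_sided_amplitude(ts, tr)
  tibble::tibble(frequency = sp$frequency, amplitude = sp$amplitude)
}

#' Fractional amplitude of low-frequency fluctuations
#'
#' fALFF of a single time series: the sum of square-root spectral power over
#' the ALFF band divided by the sum over the total analyzed range
#' (ratio-of-sums convention, so the value lies in \[0, 1\] whenever the ALFF
#' band is nested in the total band). A linear trend is removed before the
#' FFT by default. A series with zero total-band power (e.g. a constant)
#' returns 0 with a warning.
#'
#' @param ts Numeric time series, length >= 8.
#' @param tr Repetition time in seconds.
#' @param band A [band_spec()].
#' @param detrend Remove a linear trend first? Default `TRUE`.
#' @return fALFF value in \[0, 1\].
#' @export
compute_falff <- function(ts, tr, band = band_spec(), detrend = TRUE) {
  if (length(ts) < 8L) stop("need at least 8 timepoints", call. = FALSE)
  if (!all(is.finite(ts))) stop("time series contains non-finite values",
                                call. = FALSE)
  validate_band(band, tr)
  if (detrend) ts <- detrend_linear(ts)
  sp <- one_sided_amplitude(ts, tr)
  in_band <- sp$frequency >= band$low & sp$frequency <= band$high
  in_total <- sp$frequency >= band$total_low & sp$frequency <= band$total_high
  total <- sum(sp$amplitude[in_total])
  if (total <= 0) {
    warning("zero power in total band; returning fALFF = 0 for degenerate series")
    return(0)
  }
  sum(sp$amplitude[in_band]) / total
}

#' Voxelwise fALFF map
#'
#' Applies [compute_falff()] to every in-mask voxel of a 4D volume; voxels
#' outside the mask are `NaN`. Degenerate voxels (zero total-band power) get
#' fALFF 0 and are counted in a single warning.
#'
#' @param vol A `volume4d`.
#' @param mask A `brain_mask` on the same grid.
#' @param band A [band_spec()].
#' @param detrend Remove a linear trend per voxel first? Default `TRUE`.
#' @return A `stat_map` (kind `"falff_z"` after standardization; raw fALFF
#'   here).
#' @export
falff_map <- function(vol, mask, band = band_spec(), detrend = TRUE) {
  stopifnot(inherits(vol, "volume4d"), inherits(mask, "brain_mask"))
  stopifnot_same_grid(vol, mask, "volume and mask")
  validate_band(band, vol$tr)
  d <- dim(vol$data)
  nt <- d[4]
  idx <- which(mask$data)
  nvox_total <- prod(d[1:3])
  # time x voxel matrix of in-mask series
  M <- matrix(vol$data[rep(idx, nt) + rep((0:(nt - 1)) * nvox_total,
                                          each = length(idx))],
              nrow = nt, ncol = length(idx), byrow = TRUE)
  if (detrend) M <- detrend_linear(M)
  sp <- one_sided_amplitude(M, vol$tr)
  in_band <- sp$frequency >= band$low & sp$frequency <= band$high
  in_total <- sp$frequency >= band$total_low & sp$frequency <= band$total_high
  num <- colSums(sp$amplitude[in_band, , drop = FALSE])
  den <- colSums(sp$amplitude[in_total, , drop = FALSE])
  vals <- ifelse(den > 0, num / den, 0)
  n_degen <- sum(den <= 0)
  if (n_degen > 0)
    warning(n_degen, " voxel(s) had zero total-band power; fALFF set to 0")
  out <- array(NaN, d[1:3])
  out[idx] <- vals
  stat_map(out, vol$affine, "falff_z")
}

#' Fisher z-standardization
#'
#' Applies the Fisher transform `z = atanh(v)` voxelwise, the normalization
#' the pipeline uses for both fALFF maps (valid since fALFF lies in \[0, 1\))
#' and correlation maps. Values with `|v| >= 1 - 1e-7` are clipped to that
#' bound first so the output is always finite; `NaN` (out-of-mask) voxels are
#' preserved. An alternative mean/SD z-scoring across in-mask voxels is
#' available via `method = "zscore"`.
#'
#' @param map A `stat_map` or numeric vector.
#' @param method `"fisher"` (default) or `"zscore"`.
#' @return Object of the same type, transformed.
#' @export
fisher_z_standardize <- function(map, method = c("fisher", "zscore")) {
  method <- match.arg(method)
  transform <- function(v) {
    if (method == "fisher") {
      atanh(pmin(pmax(v, -(1 - 1e-7)), 1 - 1e-7))
    } else {
      fin <- is.finite(v)
      s <- stats::sd(v[fin])
      if (!is.finite(s) || s == 0) s <- 1
      (v - mean(v[fin])) / s
    }
  }
  if (inherits(map, "stat_map")) {
    out <- map
    fin <- is.finite(map$data)
    out$data[fin] <- transform(map$data[fin])
    if (method == "zscore") out$data[!fin] <- map$data[!fin]
    out
  } else {
    transform(map)
  }
}

#' Seed-based functional connectivity map
#'
#' Extracts the unweighted mean time series of the seed region and computes
#' the Pearson correlation between it and every in-mask voxel's series, then
#' Fisher z-transforms the correlations (with `|r|` clipped at `1 - 1e-7`).
#' Constant-variance voxels get `NaN`.
#'
#' @param vol A `volume4d`.
#' @param seed A `brain_mask` of the seed voxels (subset of `mask`).
#' @param mask A `brain_mask` of analysis voxels, same grid as `vol`.
#' @return A `stat_map` of kind `"fc_z"`.
#' @export
seed_fc_map <- function(vol, seed, mask) {
  stopifnot(inherits(vol, "volume4d"), inherits(seed, "brain_mask"),
            inherits(mask, "brain_mask"))
  stopifnot_same_grid(vol, mask, "volume and mask")
  stopifnot_same_grid(seed, mask, "seed and mask")
  if (any(seed$data & !mask$data))
    stop("seed must be a subset of the analysis mask", call. = FALSE)
  d <- dim(vol$data)
  nt <- d[4]
  nvox_total <- prod(d[1:3])
  sidx <- which(seed$data)
  S <- matrix(vol$data[rep(sidx, nt) + rep((0:(nt - 1)) * nvox_total,
                                           each = length(sidx))],
              nrow = nt, ncol = length(sidx), byrow = TRUE)
  s <- rowMeans(S)
  if (stats::sd(s) == 0)
    stop("seed mean time series has zero variance", call. = FALSE)
  idx <- which(mask$data)
  M <- matrix(vol$data[rep(idx, nt) + rep((0:(nt - 1)) * nvox_total,
                                          each = length(idx))],
              nrow = nt, ncol = length(idx), byrow = TRUE)
  sc <- s - mean(s)
  Mc <- sweep(M, 2L, colMeans(M))
  denom <- sqrt(sum(sc^2)) * sqrt(colSums(Mc^2))
  r <- as.vector(crossprod(sc, Mc)) / denom
  r[!is.finite(r)] <- NaN
  z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
  out <- array(NaN, d[1:3])
  out[idx] <- z
  stat_map(out, vol$affine, "fc_z")
}
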