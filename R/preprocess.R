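#' Gaussian smoothing configuration
#'
#' @param sigma_samples Kernel standard deviation in samples (> 0). The
#'   default 1.0 is the bandwidth used by the peak-refinement step.
#' @param kernel_truncation Kernel half-width as a multiple of sigma; weights
#'   beyond it are dropped and the kernel renormalized to sum 1.
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(sigma_samples = 1.0, kernel_truncation = 4.0) {
  stopifnot(sigma_samples > 0, kernel_truncation > 0)
  structure(list(sigma_samples = sigma_samples,
                 kernel_truncation = kernel_truncation),
            class = "smoothing_config")
}

#' Resample a waveform onto the canonical grid
#'
#' Samples beyond the grid window are dropped first. A waveform with more
#' native samples than the grid is downsampled by piecewise-linear
#' interpolation; one with fewer is upsampled by natural cubic-spline
#' interpolation; one already at the grid length is returned unchanged.
#'
#' @param w An [abr_waveform()] with known native times (or assumed uniform
#'   over 10 ms).
#' @param grid Target [abr_grid()].
#' @return An [abr_waveform()] whose voltages lie on the grid times.
#' @export
resample_to_grid <- function(w, grid = abr_grid()) {
  tms <- waveform_times(w, window_ms = grid$window_ms)
  keep <- tms <= grid$window_ms + 1e-9
  v <- w$voltages[keep]
  tms <- tms[keep]
  n <- length(v)
  if (n == grid$n_points) {
    out <- w
    out$times_ms <- NULL
    return(out)
  }
  if (n < 4L) stop("resampling needs at least 4 native samples")
  target <- grid_times(grid)
  newv <- if (n > grid$n_points) {
    stats::approx(tms, v, xout = target, rule = 2)$y
  } else {
    stats::spline(tms, v, xout = target, method = "natural")$y
  }
  abr_waveform(w$subject_id, w$frequency_khz, w$level_db, newv,
               source_label = w$source_label)
}

#' Resample every waveform of every stack onto the canonical grid
#'
#' @param stacks List of [abr_stack()].
#' @inheritParams resample_to_grid
#' @return List of stacks on the canonical grid.
#' @export
resample_stacks <- function(stacks, grid = abr_grid()) {
  lapply(stacks, function(s) {
    abr_stack(lapply(s$waveforms, resample_to_grid, grid = grid))
  })
}

# z-score then min-max: the composition is a single increasing affine map,
# so the output is min-max of the input; kept explicit to mirror the two
# documented scaling stages and the constant-input convention.
scale_unit_interval <- function(v, tol = 1e-12) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < tol) {
    warning("constant input to scaling; returning all 0.5")
    return(rep(0.5, length(v)))
  }
  z <- (v - mean(v)) / s
  (z - min(z)) / (max(z) - min(z))
}

#' Scale one waveform to the unit interval
#'
#' Z-scores the trace over its own timepoints, then min-max scales the
#' z-scores to `[0, 1]`. A constant (zero-variance) trace maps to all 0.5
#' with a warning. This is the per-waveform scaling used before peak-latency
#' regression.
#'
#' @param w An [abr_waveform()].
#' @return The waveform with unitless voltages in `[0, 1]`.
#' @export
scale_waveform <- function(w) {
  w$voltages <- scale_unit_interval(w$voltages)
  w
}

#' Scale a stack to the unit interval with one pooled map
#'
#' Z-scores using the mean/sd pooled over every sample of every member
#' waveform, then min-max scales the pooled values to `[0, 1]`. Because a
#' single affine map is applied to every sample, relative amplitudes across
#' levels are preserved. This is the scaling used before threshold
#' classification.
#'
#' @param s An [abr_stack()] whose members share one length.
#' @return The stack with unitless voltages; pooled min 0, pooled max 1.
#' @export
scale_stack <- function(s) {
  all_v <- unlist(lapply(s$waveforms, function(w) w$voltages))
  sd_all <- stats::sd(all_v)
  if (!is.finite(sd_all) || sd_all < 1e-12) {
    warning("constant stack in scaling; returning all 0.5")
    s$waveforms <- lapply(s$waveforms, function(w) {
      w$voltages <- rep(0.5, length(w$voltages)); w
    })
    return(s)
  }
  mu <- mean(all_v)
  z_min <- (min(all_v) - mu) / sd_all
  z_max <- (max(all_v) - mu) / sd_all
  s$waveforms <- lapply(s$waveforms, function(w) {
    z <- (w$voltages - mu) / sd_all
    w$voltages <- (z - z_min) / (z_max - z_min)
    w
  })
  s
}

gaussian_kernel <- function(sigma, truncate = 4.0) {
  r <- as.integer(ceiling(truncate * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of a voltage sequence
#'
#' Discrete convolution with a truncated, normalized Gaussian kernel.
#' Boundaries are handled by reflect padding (edge sample included in the
#' reflection), so output length equals input length and constant sequences
#' are preserved exactly.
#'
#' @param v Numeric vector.
#' @param cfg A [smoothing_config()].
#' @return Numeric vector, smoothed, same length as `v`.
#' @export
gaussian_smooth <- function(v, cfg = smoothing_config()) {
  n <- length(v)
  if (n == 0L) return(v)
  k <- gaussian_kernel(cfg$sigma_samples, cfg$kernel_truncation)
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(v)
  # reflect padding including the edge sample: (c b a | a b c ... z | z y x)
  reflect_idx <- function(i) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  idx <- vapply((1L - r):(n + r), reflect_idx, integer(1))
  vp <- v[idx]
  # direct convolution: the kernel is short, and direct evaluation avoids
  # FFT round-off dust that would break exact plateau comparisons
  out <- numeric(n)
  for (j in seq_along(k)) {
    out <- out + k[j] * vp[j:(j + n - 1L)]
  }
  out
}
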