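#' Refinement parameters for the local-extremum peak search
#'
#' The three timing constants are exact sample counts on the canonical
#' 244-point/10 ms grid: the scan starts 0.4098 ms (10 samples) before the
#' regressor's wave 1 prediction, peaks must be at least 0.6557 ms (16
#' samples) apart, and troughs at least 0.2869 ms (7 samples) apart.
#'
#' @param pre_window_ms Scan start offset before the predicted wave 1 peak.
#' @param peak_min_sep_ms Minimum separation between accepted peaks.
#' @param trough_min_sep_ms Minimum separation between accepted troughs.
#' @param smoothing [smoothing_config()] applied before the extremum scan.
#' @return An object of class `refinement_params`.
#' @export
refinement_params <- function(pre_window_ms = 0.4098,
                              peak_min_sep_ms = 0.6557,
                              trough_min_sep_ms = 0.2869,
                              smoothing = smoothing_config(1.0)) {
  stopifnot(pre_window_ms > 0, peak_min_sep_ms > 0, trough_min_sep_ms > 0)
  structure(list(pre_window_ms = pre_window_ms,
                 peak_min_sep_ms = peak_min_sep_ms,
                 trough_min_sep_ms = trough_min_sep_ms,
                 smoothing = smoothing),
            class = "refinement_params")
}

# Strict local maxima by comparison of neighboring values; a flat plateau
# counts once, at its leftmost sample. Returns 1-based indices.
local_maxima <- function(v) {
  n <- length(v)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Minimum-separation filter over extremum candidates: when two candidates
# are closer than min_sep samples, the one with the larger value survives
# (ties: leftmost). Matches the distance rule of the standard peak-picking
# routine, which suppresses small noise bumps riding next to a true peak.
enforce_min_separation <- function(idx, values, min_sep) {
  if (length(idx) == 0L) return(idx)
  ord <- order(-values, idx)
  accepted <- integer(0)
  for (i in idx[ord]) {
    if (length(accepted) == 0L || all(abs(accepted - i) >= min_sep)) {
      accepted <- c(accepted, i)
    }
  }
  sort(accepted)
}

#' Refine a wave 1 prediction into a full five-wave peak/trough set
#'
#' Implements the second stage of the two-step peak finder. The waveform is
#' Gaussian-smoothed (sigma = 1 sample); starting `pre_window_ms` before the
#' rounded regressor prediction, local maxima at least `peak_min_sep_ms`
#' apart are collected in order — the first five are waves 1-5. Local minima
#' at least `trough_min_sep_ms` apart are collected the same way, and trough
#' k is the first minimum after peak k (and before peak k+1 when present).
#' All reported voltages are read from the unsmoothed trace, so amplitudes
#' are unaffected by smoothing.
#'
#' @param w An [abr_waveform()] on the canonical grid (native uV; scaling is
#'   not required).
#' @param cnn_index Continuous predicted wave 1 sample index (0-based), e.g.
#'   from [predict_wave1_index()].
#' @param params A [refinement_params()].
#' @param grid The [abr_grid()] the waveform lies on.
#' @return An object of class `abr_peakset`: 0-based `peak_idx` and
#'   `trough_idx` (length 5, `NA` where absent), `peak_uv`/`trough_uv` from
#'   the unsmoothed trace, `wave1_latency_ms`, `wave1_amplitude_uv`, and
#'   `n_found`. A trace with no usable maximum yields an all-`NA` set rather
#'   than an error.
#' @export
refine_peaks <- function(w, cnn_index, params = refinement_params(),
                         grid = abr_grid()) {
  v <- w$voltages
  n <- length(v)
  if (n != grid$n_points) {
    stop("waveform is not on the supplied grid; resample first")
  }
  sm <- gaussian_smooth(v, params$smoothing)
  pre <- ms_to_samples(params$pre_window_ms, grid)
  peak_sep <- ms_to_samples(params$peak_min_sep_ms, grid)
  trough_sep <- ms_to_samples(params$trough_min_sep_ms, grid)
  cnn_index <- min(max(cnn_index, 0), n - 1L)
  start0 <- max(0L, as.integer(round(cnn_index)) - pre)  # 0-based

  max1 <- local_maxima(sm)                                # 1-based
  max1 <- enforce_min_separation(max1, sm[max1], peak_sep)
  peaks1 <- utils::head(max1[max1 - 1L >= start0], 5L)

  min1 <- local_maxima(-sm)
  troughs_all <- enforce_min_separation(min1, -sm[min1], trough_sep)

  peak_idx <- rep(NA_integer_, 5L)
  trough_idx <- rep(NA_integer_, 5L)
  peak_idx[seq_along(peaks1)] <- peaks1 - 1L
  for (k in seq_along(peaks1)) {
    upper <- if (k < length(peaks1)) peaks1[k + 1L] else n + 1L
    cand <- troughs_all[troughs_all > peaks1[k] & troughs_all < upper]
    if (length(cand) > 0L) trough_idx[k] <- cand[1L] - 1L
  }
  peak_uv <- ifelse(is.na(peak_idx), NA_real_, v[peak_idx + 1L])
  trough_uv <- ifelse(is.na(trough_idx), NA_real_, v[trough_idx + 1L])
  structure(
    list(peak_idx = peak_idx, trough_idx = trough_idx,
         peak_uv = peak_uv, trough_uv = trough_uv,
         wave1_latency_ms = if (is.na(peak_idx[1])) NA_real_
                            else peak_idx[1] * grid$dt_ms,
         wave1_amplitude_uv = if (is.na(peak_idx[1]) || is.na(trough_idx[1]))
                                NA_real_ else peak_uv[1] - trough_uv[1],
         n_found = sum(!is.na(peak_idx))),
    class = "abr_peakset"
  )
}

#' @export
print.abr_peakset <- function(x, ...) {
  cat(sprintf("<abr_peakset: %d/5 peaks; wave1 latency %s ms, amplitude %s uV>\n",
              x$n_found,
              if (is.na(x$wave1_latency_ms)) "NA"
              else sprintf("%.4f", x$wave1_latency_ms),
              if (is.na(x$wave1_amplitude_uv)) "NA"
              else sprintf("%.4f", x$wave1_amplitude_uv)))
  invisible(x)
}

#' Wave 1 latency and amplitude from a peak set
#'
#' Latency is the wave 1 peak index times the grid step; amplitude is the
#' peak-to-trough voltage difference read from the unsmoothed trace.
#'
#' @param ps An `abr_peakset` from [refine_peaks()].
#' @param grid The [abr_grid()].
#' @return List with `latency_ms` and `amplitude_uv` (`NA` when the peak or
#'   trough is absent).
#' @export
wave1_metrics <- function(ps, grid = abr_grid()) {
  lat <- if (is.na(ps$peak_idx[1])) NA_real_ else ps$peak_idx[1] * grid$dt_ms
  amp <- if (is.na(ps$peak_idx[1]) || is.na(ps$trough_idx[1])) NA_real_
         else ps$peak_uv[1] - ps$trough_uv[1]
  list(latency_ms = lat, amplitude_uv = amp)
}

#' Configuration of the wave 1 latency regressor
#'
#' A 1-D convolutional network: two blocks of convolution, batch
#' normalization, ReLU, max pooling and dropout, followed by two dense
#' layers ending in a single continuous output — the predicted wave 1 sample
#' index. Training minimizes (optionally per-source weighted) squared error;
#' labels are scaled to `[0, 1]` by dividing by `n_points - 1` for loss
#' stability and unscaled at prediction time.
#'
#' @param channels,kernels Convolution channels and kernel widths per block.
#' @param dropout Dropout probability after each block.
#' @param fc_units Width of the hidden dense layer.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return An object of class `peak_regressor_config`.
#' @export
peak_regressor_config <- function(channels = c(16L, 32L),
                                  kernels = c(9L, 5L), dropout = 0.05,
                                  fc_units = 64L, lr = 2e-3,
                                  batch_size = 64L, max_epochs = 80L,
                                  patience = 25L, seed = 1L) {
  structure(as.list(environment()), class = "peak_regressor_config")
}

#' Train the wave 1 latency regressor
#'
#' @param x Training matrix (rows: waveforms scaled to `[0, 1]` with
#'   [scale_waveform()]; columns: the 244 grid samples).
#' @param y True wave 1 peak indices (0-based, numeric).
#' @param xval,yval Validation set in the same form (drives early stopping).
#' @param weights Optional per-sample loss weights (e.g.
#'   [source_balanced_weights()]).
#' @param config A [peak_regressor_config()].
#' @return An object of class `abr_peak_model` (carries the fitted network
#'   and its training history).
#' @export
train_peak_regressor <- function(x, y, xval, yval, weights = NULL,
                                 config = peak_regressor_config()) {
  n_points <- ncol(x)
  set.seed(config$seed)
  net <- nn_build_cnn(n_points, config$channels, config$kernels,
                      dropout = config$dropout, fc_units = config$fc_units)
  net <- nn_fit(net, x, y / (n_points - 1), xval, yval / (n_points - 1),
                loss = "mse", weights = weights,
                max_epochs = config$max_epochs, patience = config$patience,
                lr = config$lr, batch_size = config$batch_size,
                seed = config$seed)
  structure(list(net = net, n_points = n_points, config = config,
                 fitted = TRUE),
            class = "abr_peak_model")
}

#' Predict the wave 1 peak index for scaled waveforms
#'
#' @param model A fitted `abr_peak_model`.
#' @param x Either a single [abr_waveform()] (scaled to `[0, 1]`) or a
#'   numeric matrix of scaled waveforms (rows).
#' @return Continuous 0-based sample indices clamped into
#'   `[0, n_points - 1]`; deterministic for identical input.
#' @export
predict_wave1_index <- function(model, x) {
  if (!inherits(model, "abr_peak_model") || !isTRUE(model$fitted)) {
    stop("model is not a fitted abr_peak_model")
  }
  if (inherits(x, "abr_waveform")) x <- matrix(x$voltages, nrow = 1)
  if (ncol(x) != model$n_points) stop("input length mismatch")
  pred <- nn_predict(model$net, x) * (model$n_points - 1)
  pmin(pmax(pred, 0), model$n_points - 1)
}

#' Detect peaks for every waveform of a list of stacks
#'
#' Runs the full two-step detector: per-waveform scaling, regressor
#' prediction, then [refine_peaks()] on the unscaled trace.
#'
#' @param stacks List of [abr_stack()] on the canonical grid.
#' @param model A fitted `abr_peak_model`.
#' @param params A [refinement_params()].
#' @param grid The [abr_grid()].
#' @return Data frame with one row per waveform: identifiers, wave 1
#'   latency/amplitude, and the 0-based peak/trough indices of waves 1-5.
#' @export
batch_peaks <- function(stacks, model, params = refinement_params(),
                        grid = abr_grid()) {
  m <- stacks_to_matrix(stacks)
  xs <- t(apply(m$x, 1, scale_unit_interval))
  pred <- predict_wave1_index(model, xs)
  rows <- vector("list", nrow(m$x))
  for (i in seq_len(nrow(m$x))) {
    w <- abr_waveform(m$meta$subject_id[i], m$meta$frequency_khz[i],
                      m$meta$level_db[i], m$x[i, ],
                      source_label = m$meta$source_label[i])
    ps <- refine_peaks(w, pred[i], params, grid)
    row <- data.frame(
      subject = w$subject_id, frequency_khz = w$frequency_khz,
      level_db = w$level_db, cnn_index = pred[i],
      wave1_latency_ms = ps$wave1_latency_ms,
      wave1_amplitude_uv = ps$wave1_amplitude_uv,
      stringsAsFactors = FALSE)
    for (k in 1:5) row[[paste0("peak_idx", k)]] <- ps$peak_idx[k]
    for (k in 1:5) row[[paste0("trough_idx", k)]] <- ps$trough_idx[k]
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
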