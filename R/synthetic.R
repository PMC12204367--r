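#' Configuration for the synthetic ABR generator
#'
#' The generator emulates the phenomenology the analysis models must learn:
#' five biphasic waves whose amplitudes grow and latencies shorten with
#' stimulus level, a per-stack hearing threshold below which the recording is
#' noise only, additive Gaussian recording noise, and per-subject random
#' effects so that subject-level splits are meaningful.
#'
#' Each wave k is a biphasic wavelet: a positive Gaussian lobe at latency
#' `tau_k(level)` and a negative lobe `trough_delay_ms` later. Above the
#' stack threshold the wave amplitude follows a sigmoidal growth
#' `A_k(level) = amp_max_uv[k] * plogis(amp_growth_slope * (level - threshold))`;
#' below threshold the trace is noise only. Latency shifts linearly with
#' level: `tau_k(level) = wave_latencies_ms[k] + latency_shift_per_db *
#' (level - max(levels_db))`, scaled by the subject's latency factor.
#'
#' @param n_subjects Number of subjects.
#' @param frequencies_khz Stimulus frequencies (kHz).
#' @param levels_db Stimulus levels, sorted descending (dB).
#' @param wave_latencies_ms Base latencies of waves 1-5 at the loudest level.
#' @param latency_shift_per_db Latency change per dB (negative: latency
#'   shortens as level rises).
#' @param amp_max_uv Per-wave maximum amplitudes (uV).
#' @param amp_growth_slope Sigmoidal growth rate above threshold (1/dB).
#' @param threshold_range_db Range from which per-stack true thresholds are
#'   drawn (uniform over the tested levels inside the range).
#' @param noise_sd_uv Additive Gaussian recording-noise standard deviation.
#' @param trough_delay_ms Delay of the negative lobe after the peak.
#' @param peak_width_ms,trough_width_ms Gaussian lobe widths (sd, ms).
#' @param trough_depth Negative-lobe amplitude as a fraction of the positive
#'   lobe.
#' @param subject_latency_sd,subject_amp_sd Relative spread of per-subject
#'   latency (default 10%) and amplitude (default 20%) scaling factors.
#' @param sources Named integer vector: native samples-per-window for each
#'   simulated recording source. The default is a single source already on
#'   the canonical 244-point grid; e.g. `c(labA = 244, labB = 488)`
#'   exercises resampling and per-source weighting.
#' @param grid Canonical [abr_grid()] used for ground-truth indices.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 10L,
                         frequencies_khz = c(8, 16),
                         levels_db = seq(90, 10, by = -5),
                         wave_latencies_ms = c(1.5, 2.5, 3.4, 4.4, 5.3),
                         latency_shift_per_db = -0.01,
                         amp_max_uv = c(1.5, 1.2, 1.0, 0.8, 0.7),
                         amp_growth_slope = 0.1,
                         threshold_range_db = c(25, 70),
                         noise_sd_uv = 0.15,
                         trough_delay_ms = 0.3,
                         peak_width_ms = 0.16,
                         trough_width_ms = 0.14,
                         trough_depth = 0.7,
                         subject_latency_sd = 0.10,
                         subject_amp_sd = 0.20,
                         sources = c(default = 244L),
                         grid = abr_grid(),
                         seed = 1L) {
  levels_db <- sort(as.numeric(levels_db), decreasing = TRUE)
  if (length(levels_db) == 0L || length(frequencies_khz) == 0L) {
    stop("levels_db and frequencies_khz must be non-empty")
  }
  stopifnot(length(wave_latencies_ms) == 5L, length(amp_max_uv) == 5L,
            noise_sd_uv >= 0, n_subjects >= 1L)
  if (threshold_range_db[1] > threshold_range_db[2]) {
    stop("threshold_range_db must be an increasing range")
  }
  if (!any(levels_db >= threshold_range_db[1] &
             levels_db <= threshold_range_db[2])) {
    stop("no tested level falls inside threshold_range_db")
  }
  structure(as.list(environment()), class = "synth_config")
}

# Noise-free composite signal at arbitrary times (ms).
synth_clean_signal <- function(times_ms, taus, amps, cfg) {
  v <- numeric(length(times_ms))
  for (k in seq_along(taus)) {
    if (amps[k] <= 0) next
    v <- v + amps[k] *
      (exp(-(times_ms - taus[k])^2 / (2 * cfg$peak_width_ms^2)) -
         cfg$trough_depth *
           exp(-(times_ms - taus[k] - cfg$trough_delay_ms)^2 /
                 (2 * cfg$trough_width_ms^2)))
  }
  v
}

# Latencies and amplitudes for one condition.
synth_params_at <- function(cfg, level, threshold, lat_factor = 1,
                            amp_factor = 1) {
  taus <- (cfg$wave_latencies_ms +
             cfg$latency_shift_per_db * (level - max(cfg$levels_db))) *
    lat_factor
  amps <- if (level >= threshold) {
    cfg$amp_max_uv * amp_factor *
      stats::plogis(cfg$amp_growth_slope * (level - threshold))
  } else {
    numeric(5)
  }
  list(taus = taus, amps = amps)
}

# Ground-truth peak/trough indices on the canonical grid. Peak location is
# defined on the sigma = 1 smoothed noise-free composite — the same
# bandwidth the extremum scan uses, so location truth is the quantity the
# detector estimates — as the local argmax/argmin inside a window around
# each wave's nominal latency. Amplitude truth is always read from the
# unsmoothed composite at these indices. Indices are 0-based grid samples.
synth_truth_indices <- function(clean, taus, cfg) {
  tg <- grid_times(cfg$grid)
  sm <- gaussian_smooth(clean, smoothing_config(1.0))
  peak_idx <- integer(5); trough_idx <- integer(5)
  for (k in 1:5) {
    win <- which(tg >= taus[k] - 0.3 & tg <= taus[k] + 0.3)
    peak_idx[k] <- win[which.max(sm[win])] - 1L
    twin <- which(tg > tg[peak_idx[k] + 1L] &
                    tg <= taus[k] + cfg$trough_delay_ms + 0.35)
    trough_idx[k] <- twin[which.min(sm[twin])] - 1L
  }
  list(peak_idx = peak_idx, trough_idx = trough_idx)
}

#' Generate a single synthetic ABR waveform with ground truth
#'
#' Standalone entry point for one (subject, frequency, level) condition;
#' [generate_dataset()] is the batch generator. Above `threshold_db` the
#' waveform is the five-wave composite plus noise; below it, noise only.
#'
#' @param cfg A [synth_config()].
#' @param subject,frequency,level Condition identifiers; `level` must be one
#'   of `cfg$levels_db`.
#' @param threshold_db True threshold for the stack this waveform belongs to.
#' @param lat_factor,amp_factor Per-subject scaling factors (default 1).
#' @param noise If `FALSE`, the noise term is omitted.
#' @param seed Optional seed applied before drawing noise.
#' @return List with `waveform` ([abr_waveform()] on the canonical grid) and
#'   `truth` (one-row data frame of true indices, latency, amplitude and the
#'   supra-threshold flag).
#' @export
generate_waveform <- function(cfg, subject, frequency, level, threshold_db,
                              lat_factor = 1, amp_factor = 1, noise = TRUE,
                              seed = NULL) {
  if (!level %in% cfg$levels_db) stop("level not in cfg$levels_db")
  if (!is.null(seed)) set.seed(seed)
  pars <- synth_params_at(cfg, level, threshold_db, lat_factor, amp_factor)
  tg <- grid_times(cfg$grid)
  clean <- synth_clean_signal(tg, pars$taus, pars$amps, cfg)
  v <- clean
  if (noise && cfg$noise_sd_uv > 0) {
    v <- v + stats::rnorm(length(v), sd = cfg$noise_sd_uv)
  }
  above <- level >= threshold_db
  if (above) {
    ti <- synth_truth_indices(clean, pars$taus, cfg)
    p1 <- ti$peak_idx[1]; t1 <- ti$trough_idx[1]
    truth <- data.frame(
      subject = as.character(subject), frequency_khz = frequency,
      level_db = level, above_threshold = TRUE,
      wave1_latency_ms = p1 * cfg$grid$dt_ms,
      wave1_amplitude_uv = clean[p1 + 1L] - clean[t1 + 1L],
      stringsAsFactors = FALSE)
    for (k in 1:5) truth[[paste0("peak_idx", k)]] <- ti$peak_idx[k]
    for (k in 1:5) truth[[paste0("trough_idx", k)]] <- ti$trough_idx[k]
  } else {
    truth <- data.frame(
      subject = as.character(subject), frequency_khz = frequency,
      level_db = level, above_threshold = FALSE,
      wave1_latency_ms = NA_real_, wave1_amplitude_uv = NA_real_,
      stringsAsFactors = FALSE)
    for (k in 1:5) truth[[paste0("peak_idx", k)]] <- NA_integer_
    for (k in 1:5) truth[[paste0("trough_idx", k)]] <- NA_integer_
  }
  list(waveform = abr_waveform(subject, frequency, level, v),
       truth = truth)
}

#' Generate a full synthetic dataset of ABR stacks with ground truth
#'
#' Produces `n_subjects * length(frequencies_khz)` stacks, each with one
#' waveform per tested level, plus a ground-truth record for every waveform
#' and a true threshold for every stack. The whole dataset is a deterministic
#' function of `cfg$seed`.
#'
#' When `cfg$sources` names several native sampling rates, subjects are
#' assigned to sources round-robin and waveforms are generated on the native
#' grid (resample with [resample_stacks()] before analysis). Ground-truth
#' indices always refer to the canonical grid.
#'
#' @param cfg A [synth_config()].
#' @return List with `stacks` (list of [abr_stack()]), `truth` (list with
#'   `waveforms` and `stacks` data frames) and `cfg`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  src_names <- names(cfg$sources)
  if (is.null(src_names)) src_names <- paste0("src", seq_along(cfg$sources))
  # per-stack thresholds are drawn from tested levels inside the range
  thr_levels <- cfg$levels_db[cfg$levels_db >= cfg$threshold_range_db[1] &
                                cfg$levels_db <= cfg$threshold_range_db[2]]
  if (length(thr_levels) == 0L) stop("no tested level in threshold range")

  stacks <- list(); wf_truth <- list(); st_truth <- list()
  tg <- grid_times(cfg$grid)
  for (si in seq_len(cfg$n_subjects)) {
    subject <- sprintf("S%03d", si)
    src_i <- ((si - 1L) %% length(cfg$sources)) + 1L
    n_native <- cfg$sources[[src_i]]
    # truncated at +/- 2 sd: keeps inter-wave spacing above the 0.6557 ms
    # peak-separation constant, so the refinement problem stays solvable
    lat_factor <- min(1 + 2 * cfg$subject_latency_sd,
                      max(1 - 2 * cfg$subject_latency_sd,
                          1 + stats::rnorm(1, sd = cfg$subject_latency_sd)))
    amp_factor <- min(1 + 2 * cfg$subject_amp_sd,
                      max(1 - 2 * cfg$subject_amp_sd,
                          1 + stats::rnorm(1, sd = cfg$subject_amp_sd)))
    for (fq in cfg$frequencies_khz) {
      threshold <- thr_levels[sample.int(length(thr_levels), 1L)]
      waves <- list()
      for (level in cfg$levels_db) {
        pars <- synth_params_at(cfg, level, threshold, lat_factor,
                                amp_factor)
        native_t <- (seq_len(n_native) - 1) * (cfg$grid$window_ms / n_native)
        clean_native <- synth_clean_signal(native_t, pars$taus, pars$amps,
                                           cfg)
        v <- clean_native
        if (cfg$noise_sd_uv > 0) {
          v <- v + stats::rnorm(n_native, sd = cfg$noise_sd_uv)
        }
        waves[[length(waves) + 1L]] <- abr_waveform(
          subject, fq, level, v,
          times_ms = if (n_native == cfg$grid$n_points) NULL else native_t,
          source_label = src_names[src_i])
        above <- level >= threshold
        clean_grid <- synth_clean_signal(tg, pars$taus, pars$amps, cfg)
        rec <- data.frame(
          subject = subject, frequency_khz = fq, level_db = level,
          source_label = src_names[src_i], above_threshold = above,
          wave1_latency_ms = NA_real_, wave1_amplitude_uv = NA_real_,
          stringsAsFactors = FALSE)
        for (k in 1:5) rec[[paste0("peak_idx", k)]] <- NA_integer_
        for (k in 1:5) rec[[paste0("trough_idx", k)]] <- NA_integer_
        if (above) {
          ti <- synth_truth_indices(clean_grid, pars$taus, cfg)
          rec$wave1_latency_ms <- ti$peak_idx[1] * cfg$grid$dt_ms
          rec$wave1_amplitude_uv <- clean_grid[ti$peak_idx[1] + 1L] -
            clean_grid[ti$trough_idx[1] + 1L]
          for (k in 1:5) rec[[paste0("peak_idx", k)]] <- ti$peak_idx[k]
          for (k in 1:5) rec[[paste0("trough_idx", k)]] <- ti$trough_idx[k]
        }
        wf_truth[[length(wf_truth) + 1L]] <- rec
      }
      stacks[[length(stacks) + 1L]] <- abr_stack(waves)
      st_truth[[length(st_truth) + 1L]] <- data.frame(
        subject = subject, frequency_khz = fq, threshold_db = threshold,
        source_label = src_names[src_i], stringsAsFactors = FALSE)
    }
  }
  names(stacks) <- vapply(stacks, function(s) {
    paste(s$subject_id, s$frequency_khz, sep = "|")
  }, character(1))
  list(stacks = stacks,
       truth = list(waveforms = do.call(rbind, wf_truth),
                    stacks = do.call(rbind, st_truth)),
       cfg = cfg)
}
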