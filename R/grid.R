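#' Canonical ABR sampling grid
#'
#' ABR waveforms are analyzed on a fixed grid of `n_points` samples spanning
#' `window_ms` milliseconds post-stimulus. Sample `i` (0-based) maps to time
#' `i * dt_ms` with `dt_ms = window_ms / n_points`. The default 244-point /
#' 10 ms grid makes the refinement constants 0.4098, 0.6557 and 0.2869 ms
#' exact integer sample counts (10, 16 and 7).
#'
#' @param n_points Number of samples (default 244).
#' @param window_ms Post-stimulus window length in ms (default 10).
#' @return An object of class `abr_grid` with fields `n_points`, `window_ms`,
#'   `dt_ms`.
#' @examples
#' g <- abr_grid()
#' g$dt_ms * g$n_points  # == 10
#' @export
abr_grid <- function(n_points = 244L, window_ms = 10) {
  n_points <- as.integer(n_points)
  stopifnot(n_points >= 2L, is.finite(window_ms), window_ms > 0)
  structure(
    list(n_points = n_points, window_ms = window_ms,
         dt_ms = window_ms / n_points),
    class = "abr_grid"
  )
}

#' Sample times of a grid
#'
#' @param grid An [abr_grid()].
#' @return Numeric vector of length `n_points`: time (ms) of each sample,
#'   starting at 0.
#' @export
grid_times <- function(grid) {
  (seq_len(grid$n_points) - 1) * grid$dt_ms
}

#' Convert a duration in ms to a whole number of samples
#'
#' @param ms Duration in milliseconds.
#' @param grid An [abr_grid()].
#' @return Integer sample count, `round(ms / dt_ms)`.
#' @export
ms_to_samples <- function(ms, grid = abr_grid()) {
  as.integer(round(ms / grid$dt_ms))
}

#' @export
print.abr_grid <- function(x, ...) {
  cat(sprintf("<abr_grid: %d points / %.4g ms (dt = %.6g ms)>\n",
              x$n_points, x$window_ms, x$dt_ms))
  invisible(x)
}

#' Single ABR waveform
#'
#' One voltage trace recorded at a (subject, stimulus frequency, stimulus
#' level) condition. Voltages are in microvolts unless stated otherwise.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param frequency_khz Stimulus frequency in kHz (> 0).
#' @param level_db Stimulus level in dB.
#' @param voltages Numeric vector of voltages (uV).
#' @param times_ms Optional native sample times (ms). When `NULL` a uniform
#'   grid over 10 ms with `length(voltages)` points is assumed.
#' @param source_label Identifier for the recording source (lab); used for
#'   per-source loss weighting.
#' @return An object of class `abr_waveform`.
#' @export
abr_waveform <- function(subject_id, frequency_khz, level_db, voltages,
                         times_ms = NULL, source_label = "default") {
  voltages <- as.numeric(voltages)
  if (!all(is.finite(voltages))) {
    stop("waveform voltages must all be finite")
  }
  if (!is.finite(frequency_khz) || frequency_khz <= 0) {
    stop("frequency_khz must be a positive number")
  }
  if (!is.null(times_ms)) {
    times_ms <- as.numeric(times_ms)
    if (length(times_ms) != length(voltages)) {
      stop("times_ms and voltages must have equal length")
    }
    if (any(diff(times_ms) <= 0)) {
      stop("times_ms must be strictly increasing")
    }
  }
  structure(
    list(subject_id = as.character(subject_id),
         frequency_khz = as.numeric(frequency_khz),
         level_db = as.numeric(level_db),
         voltages = voltages,
         times_ms = times_ms,
         source_label = as.character(source_label)),
    class = "abr_waveform"
  )
}

#' Native sample times of a waveform
#'
#' @param w An [abr_waveform()].
#' @param window_ms Window assumed when the waveform carries no explicit time
#'   axis.
#' @return Numeric vector of times (ms).
#' @export
waveform_times <- function(w, window_ms = 10) {
  if (!is.null(w$times_ms)) return(w$times_ms)
  n <- length(w$voltages)
  (seq_len(n) - 1) * (window_ms / n)
}

#' @export
print.abr_waveform <- function(x, ...) {
  cat(sprintf(
    "<abr_waveform: subject %s, %.4g kHz, %g dB, %d samples [%s]>\n",
    x$subject_id, x$frequency_khz, x$level_db, length(x$voltages),
    x$source_label))
  invisible(x)
}

#' ABR stack: one subject x frequency across stimulus levels
#'
#' A stack is the unit of hearing-threshold estimation: the family of
#' waveforms recorded from one subject at one stimulus frequency across
#' descending stimulus levels. Member waveforms are stored sorted by level,
#' loudest first.
#'
#' @param waveforms List of [abr_waveform()] sharing subject and frequency.
#' @return An object of class `abr_stack` with fields `subject_id`,
#'   `frequency_khz`, `levels_db` (descending) and `waveforms`.
#' @export
abr_stack <- function(waveforms) {
  if (length(waveforms) < 1L) stop("a stack needs at least one waveform")
  subj <- unique(vapply(waveforms, function(w) w$subject_id, character(1)))
  freq <- unique(vapply(waveforms, function(w) w$frequency_khz, numeric(1)))
  if (length(subj) != 1L || length(freq) != 1L) {
    stop("all waveforms in a stack must share subject_id and frequency_khz")
  }
  lv <- vapply(waveforms, function(w) w$level_db, numeric(1))
  if (anyDuplicated(lv)) {
    stop(sprintf("duplicate level(s) in stack (subject %s, %.4g kHz): %s",
                 subj, freq,
                 paste(unique(lv[duplicated(lv)]), collapse = ", ")))
  }
  ord <- order(lv, decreasing = TRUE)
  structure(
    list(subject_id = subj, frequency_khz = freq,
         levels_db = lv[ord], waveforms = waveforms[ord]),
    class = "abr_stack"
  )
}

#' @export
print.abr_stack <- function(x, ...) {
  cat(sprintf("<abr_stack: subject %s, %.4g kHz, %d levels (%g..%g dB)>\n",
              x$subject_id, x$frequency_khz, length(x$levels_db),
              max(x$levels_db), min(x$levels_db)))
  invisible(x)
}

#' @export
length.abr_stack <- function(x) length(x$waveforms)

#' Flatten a list of stacks into a feature matrix plus metadata
#'
#' Convenience for model training: one row per waveform, columns are the
#' voltages (all waveforms must share a common length, e.g. after
#' [resample_to_grid()]).
#'
#' @param stacks List of [abr_stack()].
#' @return List with `x` (numeric matrix, n x n_points) and `meta`
#'   (data.frame: subject_id, frequency_khz, level_db, source_label,
#'   stack_index).
#' @export
stacks_to_matrix <- function(stacks) {
  rows <- list(); meta <- list(); r <- 0L
  for (si in seq_along(stacks)) {
    s <- stacks[[si]]
    for (w in s$waveforms) {
      r <- r + 1L
      rows[[r]] <- w$voltages
      meta[[r]] <- data.frame(
        subject_id = w$subject_id, frequency_khz = w$frequency_khz,
        level_db = w$level_db, source_label = w$source_label,
        stack_index = si, stringsAsFactors = FALSE)
    }
  }
  lens <- lengths(rows)
  if (length(unique(lens)) > 1L) {
    stop("waveforms have unequal lengths; resample to a common grid first")
  }
  list(x = do.call(rbind, rows), meta = do.call(rbind, meta))
}
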