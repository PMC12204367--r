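#' Elastic time warping of a stack onto a reference waveform
#'
#' Aligns the peaks of every member waveform to those of a reference
#' (default: the loudest level) by landmark-guided piecewise-linear warping.
#' Landmarks are detected local maxima of the smoothed trace (up to five,
#' under the standard peak-separation rule); each is matched to the nearest
#' reference landmark within `match_window_ms`, non-monotone matches are
#' dropped, and the warp is the piecewise-linear monotone map through the
#' matched pairs with fixed endpoints. Warped traces are re-evaluated by
#' linear interpolation between grid samples, so amplitudes change only by
#' interpolation error, and exactly the landmark samples are preserved.
#' Waveforms with no usable landmarks (e.g. sub-threshold, noise-only
#' traces) receive the identity warp.
#'
#' @param s An [abr_stack()] on the canonical grid with at least one
#'   waveform.
#' @param reference `"loudest"` (default) or the index of the member
#'   waveform to align to.
#' @param peaksets Optional list of `abr_peakset`s (one per member, in stack
#'   order) to use as landmarks instead of the built-in detector.
#' @param params [refinement_params()] for the built-in landmark detector.
#' @param grid The [abr_grid()].
#' @param match_window_ms Maximum landmark-to-reference distance for a
#'   match.
#' @param snr_min Minimum (max - median) / mad ratio of the smoothed trace
#'   for a waveform to be considered landmark-bearing; pure recording noise
#'   scores about 2.7 on this statistic regardless of its sd, supra-threshold
#'   responses well above 4.
#' @return List of class `abr_alignment`: `stack` (aligned copy) and
#'   `warps` (per member, the warp evaluated at the grid times: monotone,
#'   gamma(0) = 0, gamma(end) = end).
#' @export
align_stack <- function(s, reference = "loudest", peaksets = NULL,
                        params = refinement_params(), grid = abr_grid(),
                        match_window_ms = 0.6, snr_min = 4.5) {
  if (length(s$waveforms) < 1L) stop("empty stack")
  ref_i <- if (identical(reference, "loudest")) 1L else as.integer(reference)
  tg <- grid_times(grid)
  end_ms <- tg[length(tg)]

  get_landmarks <- function(i) {
    if (!is.null(peaksets)) {
      idx <- peaksets[[i]]$peak_idx
      return(idx[!is.na(idx)] * grid$dt_ms)
    }
    v <- s$waveforms[[i]]$voltages
    sm <- gaussian_smooth(v, params$smoothing)
    noise_scale <- stats::mad(sm)
    if (noise_scale < 1e-12 ||
        (max(sm) - stats::median(sm)) / noise_scale < snr_min) {
      return(numeric(0))
    }
    cand <- local_maxima(sm)
    # keep prominent maxima only: above the trace median by 25% of range
    hi <- sm[cand] > stats::median(sm) + 0.25 * (max(sm) - min(sm))
    cand <- cand[hi]
    cand <- enforce_min_separation(cand, sm[cand],
                                   ms_to_samples(params$peak_min_sep_ms,
                                                 grid))
    utils::head(cand - 1L, 5L) * grid$dt_ms
  }

  lm <- lapply(seq_along(s$waveforms), get_landmarks)
  ref_lm <- lm[[ref_i]]

  warps <- vector("list", length(s$waveforms))
  aligned <- s$waveforms
  for (i in seq_along(s$waveforms)) {
    v <- s$waveforms[[i]]$voltages
    if (i == ref_i || length(ref_lm) == 0L || length(lm[[i]]) == 0L) {
      warps[[i]] <- tg
      next
    }
    # match each landmark to nearest reference landmark within the window
    src <- numeric(0); dst <- numeric(0)
    for (l in lm[[i]]) {
      j <- which.min(abs(ref_lm - l))
      if (abs(ref_lm[j] - l) <= match_window_ms) {
        src <- c(src, l); dst <- c(dst, ref_lm[j])
      }
    }
    # enforce strict monotonicity of the knot set (drop violators)
    keep <- rep(TRUE, length(src))
    if (length(src) > 1L) {
      for (j in 2:length(src)) {
        prev <- max(which(keep[seq_len(j - 1L)]), -Inf)
        if (is.finite(prev) &&
            (src[j] <= src[prev] || dst[j] <= dst[prev])) keep[j] <- FALSE
      }
    }
    src <- src[keep]; dst <- dst[keep]
    dup <- duplicated(dst)
    src <- src[!dup]; dst <- dst[!dup]
    inner <- dst > 0 & dst < end_ms & src > 0 & src < end_ms
    src <- src[inner]; dst <- dst[inner]
    if (length(src) == 0L) {
      warps[[i]] <- tg
      next
    }
    gamma <- stats::approx(c(0, dst, end_ms), c(0, src, end_ms),
                           xout = tg)$y
    warps[[i]] <- gamma
    aligned[[i]]$voltages <- stats::approx(tg, v, xout = gamma)$y
  }
  structure(list(stack = abr_stack(aligned), warps = warps,
                 reference = ref_i),
            class = "abr_alignment")
}
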