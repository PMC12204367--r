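# Independent brute-force oracles used to pin expected values. These are
# deliberately naive re-implementations, kept free of any package internals.

# Two-point linear interpolation, one query at a time.
brute_linear_interp <- function(x, y, xout) {
  vapply(xout, function(q) {
    if (q <= x[1]) return(y[1])
    n <- length(x)
    if (q >= x[n]) return(y[n])
    j <- max(which(x <= q))
    if (x[j] == q) return(y[j])
    y[j] + (y[j + 1] - y[j]) * (q - x[j]) / (x[j + 1] - x[j])
  }, numeric(1))
}

# Natural cubic spline by direct solution of the tridiagonal system for the
# second derivatives, then piecewise cubic evaluation.
brute_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, rhs)                       # second derivatives at the knots
  # natural-spline convention: linear extrapolation with the boundary slope
  slope1 <- (y[2] - y[1]) / h[1] - h[1] * (2 * M[1] + M[2]) / 6
  slopen <- (y[n] - y[n - 1]) / h[n - 1] +
    h[n - 1] * (M[n - 1] + 2 * M[n]) / 6
  vapply(xout, function(q) {
    if (q < x[1]) return(y[1] + slope1 * (q - x[1]))
    if (q > x[n]) return(y[n] + slopen * (q - x[n]))
    j <- max(which(x <= q))
    if (j == n) j <- n - 1
    hj <- h[j]
    a <- (x[j + 1] - q) / hj
    b <- (q - x[j]) / hj
    a * y[j] + b * y[j + 1] +
      ((a^3 - a) * M[j] + (b^3 - b) * M[j + 1]) * hj^2 / 6
  }, numeric(1))
}

# Direct double-loop Gaussian convolution with edge-inclusive symmetric
# reflection, matching the documented boundary convention.
brute_gaussian_smooth <- function(v, sigma = 1, truncate = 4) {
  n <- length(v)
  r <- as.integer(ceiling(truncate * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect <- function(i) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in (-r):r) acc <- acc + k[j + r + 1] * v[reflect(i + j)]
    out[i] <- acc
  }
  out
}

# Pairwise-concordance AUC with half credit for ties.
brute_concordance_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# Literal transcription of the threshold rules.
brute_threshold <- function(levels, calls, rule) {
  ord <- order(levels, decreasing = TRUE)
  levels <- levels[ord]; calls <- calls[ord]
  if (rule == "literal") {
    pos <- levels[calls == 1]
    if (length(pos) == 0) return(Inf)
    return(min(pos))
  }
  # contiguous: walk down from the loudest while positive
  thr <- Inf
  for (i in seq_along(levels)) {
    if (calls[i] == 1) thr <- levels[i] else break
  }
  thr
}

# Small helper: one noise-free five-wave waveform plus its truth row.
make_clean_waveform <- function(level = 80, threshold = 40, seed = 1,
                                lat_factor = 1, amp_factor = 1) {
  cfg <- synth_config(noise_sd_uv = 0, seed = seed)
  generate_waveform(cfg, "S1", 16, level, threshold,
                    lat_factor = lat_factor, amp_factor = amp_factor,
                    noise = FALSE)
}
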