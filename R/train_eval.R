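#' Subject-level train/validation/test split
#'
#' Splits are by subject, never by waveform: within each source (lab), 80%
#' of subjects go to the training pool and 20% to the test set, then 20% of
#' the training-pool subjects are held out for validation. Counts are
#' rounded to the nearest subject with a minimum of one per partition;
#' subjects are shuffled with the given seed before cutting, so the split is
#' reproducible.
#'
#' @param meta Data frame with columns `subject_id` and `source_label` (one
#'   row per waveform is fine; unique subjects are extracted).
#' @param train_frac Fraction of each source's subjects in the training
#'   pool (default 0.8).
#' @param val_frac Fraction of the training pool held out for validation
#'   (default 0.2).
#' @param seed Shuffling seed.
#' @return List with character vectors `train`, `val`, `test` of subject
#'   ids; the three are disjoint and exhaust the subjects of every source.
#' @export
split_by_subject <- function(meta, train_frac = 0.8, val_frac = 0.2,
                             seed = 1L) {
  stopifnot(all(c("subject_id", "source_label") %in% names(meta)))
  subj <- unique(meta[, c("subject_id", "source_label")])
  set.seed(seed)
  train <- character(0); val <- character(0); test <- character(0)
  for (src in unique(subj$source_label)) {
    ids <- subj$subject_id[subj$source_label == src]
    n <- length(ids)
    if (n < 3L) {
      stop(sprintf("source %s has %d subject(s); at least 3 are needed",
                   src, n))
    }
    ids <- sample(ids)
    n_test <- max(1L, round((1 - train_frac) * n))
    n_pool <- n - n_test
    n_val <- max(1L, round(val_frac * n_pool))
    n_train <- n_pool - n_val
    if (n_train < 1L) stop(sprintf("source %s too small for three partitions",
                                   src))
    train <- c(train, ids[seq_len(n_train)])
    val <- c(val, ids[n_train + seq_len(n_val)])
    test <- c(test, ids[n_pool + seq_len(n_test)])
  }
  list(train = train, val = val, test = test)
}

#' Per-sample weights balancing the contribution of each source
#'
#' Weight `w_i = N / (S * n_source(i))` with `N` total samples, `S` the
#' number of sources and `n_source` the size of sample i's source, so every
#' source's weights sum to `N / S` and the weights total `N`.
#'
#' @param source_labels Character vector of source (lab) labels, one per
#'   sample.
#' @return Numeric weight vector of the same length.
#' @export
source_balanced_weights <- function(source_labels) {
  n <- length(source_labels)
  if (n == 0L) return(numeric(0))
  tab <- table(source_labels)
  s <- length(tab)
  as.numeric(n / (s * tab[source_labels]))
}

#' Augment a training matrix of scaled waveforms
#'
#' Produces exactly one augmented copy per original row (doubling the
#' training set); the augmentation kind is drawn uniformly per sample from
#' `kinds`. Kinds: `noise` adds Gaussian noise; `elastic` jitters spline
#' control points along the time axis and re-evaluates the trace by cubic
#' spline interpolation; `shift` translates by a random whole number of
#' samples (edge-replicated, magnitude clamped to `shift_max`).
#'
#' @param x Numeric matrix, one scaled waveform per row.
#' @param kinds Subset of `c("noise", "elastic", "shift")`.
#' @param noise_sd Noise sd as a fraction of the scaled range.
#' @param elastic_jitter Control-point jitter in samples.
#' @param shift_max Maximum shift in samples.
#' @param seed RNG seed; a fixed seed reproduces the augmented set exactly.
#' @return List with `x` (the `2n x p` matrix: originals then copies),
#'   `origin` (row index each row derives from) and `kind` (`"original"` or
#'   the augmentation kind).
#' @export
augment_waveforms <- function(x, kinds = c("noise", "elastic", "shift"),
                              noise_sd = 0.02, elastic_jitter = 2,
                              shift_max = 3L, seed = 1L) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  aug <- matrix(0, n, p)
  kind <- sample(kinds, n, replace = TRUE)
  for (i in seq_len(n)) {
    v <- x[i, ]
    aug[i, ] <- switch(
      kind[i],
      noise = v + stats::rnorm(p, sd = noise_sd),
      elastic = {
        knots <- seq(1, p, length.out = 9)
        jit <- c(0, stats::runif(7, -elastic_jitter, elastic_jitter), 0)
        warped <- stats::approx(knots + jit, knots, xout = seq_len(p),
                                rule = 2)$y
        stats::spline(seq_len(p), v, xout = warped, method = "natural")$y
      },
      shift = {
        k <- if (shift_max == 0L) 0L
             else sample(seq(-shift_max, shift_max), 1L)
        if (k == 0L) v
        else if (k > 0L) c(rep(v[1], k), v[seq_len(p - k)])
        else c(v[(-k + 1):p], rep(v[p], -k))
      })
  }
  list(x = rbind(x, aug),
       origin = c(seq_len(n), seq_len(n)),
       kind = c(rep("original", n), kind))
}

#' Early-stopping decision for a sequence of validation losses
#'
#' Training halts after the first epoch at which the validation loss has not
#' improved (strictly decreased below the running best) for `patience`
#' consecutive epochs; the best epoch's weights are the ones kept.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Number of non-improving epochs tolerated (default 25).
#' @return List with `stop_epoch` (the epoch training halts after, or
#'   `length(val_losses)` if the patience is never exhausted), `best_epoch`
#'   and `stopped_early`.
#' @export
early_stopping_trace <- function(val_losses, patience = 25L) {
  stopifnot(patience >= 1L)
  best <- Inf; best_epoch <- 0L; since <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e; since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) {
        return(list(stop_epoch = e, best_epoch = best_epoch,
                    stopped_early = TRUE))
      }
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch,
       stopped_early = FALSE)
}

# Trapezoidal ROC over the unique score thresholds; equals the
# pairwise-concordance (Mann-Whitney) statistic with half credit for ties.
auc_roc <- function(scores, labels) {
  pos <- labels == 1; neg <- !pos
  np <- sum(pos); nn <- sum(neg)
  if (np == 0L || nn == 0L) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores[pos] >= t), numeric(1)) / np)
  fpr <- c(0, vapply(thr, function(t) sum(scores[neg] >= t), numeric(1)) / nn)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Precision-recall step integration (average-precision form).
auc_pr <- function(scores, labels) {
  pos <- labels == 1
  np <- sum(pos)
  if (np == 0L || all(pos)) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  rec <- 0; ap <- 0
  for (t in thr) {
    sel <- scores >= t
    r <- sum(pos & sel) / np
    p <- sum(pos & sel) / sum(sel)
    ap <- ap + (r - rec) * p
    rec <- r
  }
  ap
}

#' Evaluate a binary classifier
#'
#' Computes accuracy, TPR, FPR, TNR at the operating point, trapezoidal
#' AUCROC, step-integrated AUCPR, and (optionally) seeded percentile
#' bootstrap confidence intervals. "Above threshold" is the positive class.
#'
#' @param scores Scores in `[0, 1]`.
#' @param labels Binary labels (1 = positive).
#' @param cutoff Operating point (default 0.5).
#' @param n_boot Bootstrap resamples for the CIs (default 2000); 0 disables.
#' @param conf Confidence level.
#' @param seed Bootstrap seed.
#' @return List of class `abr_eval_report` with the metrics and, when
#'   bootstrapped, a `ci` data frame. AUCs are `NA` when only one class is
#'   present.
#' @export
evaluate_classifier <- function(scores, labels, cutoff = 0.5,
                                n_boot = 2000L, conf = 0.95, seed = 1L) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels > 0)
  calls <- as.integer(scores >= cutoff)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  metrics <- function(sc, lb) {
    cl <- as.integer(sc >= cutoff)
    c(accuracy = mean(cl == lb),
      tpr = if (sum(lb) > 0) sum(cl == 1 & lb == 1) / sum(lb) else NA_real_,
      fpr = if (sum(1 - lb) > 0) sum(cl == 1 & lb == 0) / sum(1 - lb)
            else NA_real_,
      aucroc = auc_roc(sc, lb),
      aucpr = auc_pr(sc, lb))
  }
  m <- metrics(scores, labels)
  report <- list(accuracy = unname(m["accuracy"]), tpr = unname(m["tpr"]),
                 fpr = unname(m["fpr"]), tnr = unname(1 - m["fpr"]),
                 aucroc = unname(m["aucroc"]), aucpr = unname(m["aucpr"]),
                 n = length(labels), n_pos = np, n_neg = nn)
  if (n_boot > 0L) {
    set.seed(seed)
    n <- length(labels)
    bs <- matrix(NA_real_, n_boot, length(m))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      bs[b, ] <- metrics(scores[idx], labels[idx])
    }
    a <- (1 - conf) / 2
    ci <- t(apply(bs, 2, stats::quantile, probs = c(a, 1 - a),
                  na.rm = TRUE))
    report$ci <- data.frame(metric = names(m), lower = ci[, 1],
                            upper = ci[, 2], row.names = NULL)
  }
  structure(report, class = "abr_eval_report")
}

#' @export
print.abr_eval_report <- function(x, ...) {
  cat(sprintf(paste0("<abr_eval_report: n = %d (%d pos / %d neg)\n",
                     "  accuracy %.4f  TPR %.4f  FPR %.4f\n",
                     "  AUCROC %s  AUCPR %s>\n"),
              x$n, x$n_pos, x$n_neg, x$accuracy, x$tpr, x$fpr,
              ifelse(is.na(x$aucroc), "NA", sprintf("%.4f", x$aucroc)),
              ifelse(is.na(x$aucpr), "NA", sprintf("%.4f", x$aucpr))))
  invisible(x)
}

#' Evaluate peak latency/amplitude predictions against ground truth
#'
#' @param pred,truth Paired numeric vectors (same length).
#' @param n_boot Bootstrap resamples for the RMSE/MAE CIs; 0 disables.
#' @param conf Confidence level.
#' @param seed Bootstrap seed.
#' @return List with `rmse`, `mae`, `mean_error`, `sem` (standard error of
#'   the mean error) and optional percentile CIs.
#' @export
evaluate_peaks <- function(pred, truth, n_boot = 2000L, conf = 0.95,
                           seed = 1L) {
  if (length(pred) != length(truth)) stop("pred/truth length mismatch")
  err <- pred - truth
  out <- list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
              mean_error = mean(err),
              sem = stats::sd(err) / sqrt(length(err)),
              n = length(err))
  if (n_boot > 0L) {
    set.seed(seed)
    bs <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      e <- err[sample.int(length(err), replace = TRUE)]
      bs[b, ] <- c(sqrt(mean(e^2)), mean(abs(e)))
    }
    a <- (1 - conf) / 2
    q <- apply(bs, 2, stats::quantile, probs = c(a, 1 - a))
    out$rmse_ci <- unname(q[, 1])
    out$mae_ci <- unname(q[, 2])
  }
  out
}

#' Proportion of threshold estimates within k dB of the truth
#'
#' A pair where both values are `Inf` (no response) counts as a hit; a pair
#' where exactly one is `Inf` counts as a miss. The number of no-response
#' pairs is attached as attribute `n_noresponse`.
#'
#' @param pred,truth Paired thresholds in dB (`Inf` = no response).
#' @param k Envelope half-width in dB.
#' @return Proportion in `[0, 1]`.
#' @export
within_k_db <- function(pred, truth, k) {
  if (length(pred) != length(truth)) stop("pred/truth length mismatch")
  both_nr <- is.infinite(pred) & is.infinite(truth)
  one_nr <- xor(is.infinite(pred), is.infinite(truth))
  hit <- both_nr | (!one_nr & !both_nr & abs(pred - truth) <= k)
  hit[is.na(hit)] <- FALSE
  structure(mean(hit), n_noresponse = sum(both_nr | one_nr))
}

#' Two-sample proportion comparison
#'
#' Pooled two-sample z-test on proportions with an unpooled-SE confidence
#' interval for the difference; the p-value can be Bonferroni-adjusted.
#' Degenerate inputs (both proportions 0 or 1) give a collapsed CI and
#' p-value 1 when the proportions are equal.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param conf Confidence level.
#' @param bonferroni_m Number of comparisons to adjust for (default 1, no
#'   adjustment); the p-value is multiplied by it and capped at 1.
#' @return List with `p1`, `p2`, `difference`, `ci`, `z`, `p_value`.
#' @export
compare_proportions <- function(x1, n1, x2, n2, conf = 0.95,
                                bonferroni_m = 1L) {
  stopifnot(n1 >= 1L, n2 >= 1L, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se_pool <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se_pool == 0) 0 else (p1 - p2) / se_pool
  p <- if (se_pool == 0 && p1 != p2) 0 else 2 * stats::pnorm(-abs(z))
  p <- min(1, p * bonferroni_m)
  se_diff <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  list(p1 = p1, p2 = p2, difference = p1 - p2,
       ci = c(p1 - p2 - zq * se_diff, p1 - p2 + zq * se_diff),
       z = z, p_value = p)
}
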