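#' Configuration of the supra-threshold waveform classifier
#'
#' Three model families are supported, mirroring the candidate classifiers
#' of the threshold-estimation method:
#' \describe{
#'   \item{`cnn`}{Three blocks of convolution, batch normalization, ReLU,
#'     max pooling and dropout, two dense layers and a sigmoid head; trained
#'     on stack-scaled waveforms with weighted binary cross-entropy.}
#'   \item{`xgboost`}{Gradient-boosted trees on the 244 voltage features
#'     (time-warp-aligned input).}
#'   \item{`logistic`}{Ridge-regularized logistic regression on the same
#'     features (time-warp-aligned input).}
#' }
#' "Above threshold" is the positive class. The 244 scaled voltages are the
#' only features; frequency and level are deliberately not inputs.
#'
#' @param family One of `"cnn"`, `"xgboost"`, `"logistic"`.
#' @param channels,kernels,dropout,fc_units CNN architecture (family
#'   `"cnn"`).
#' @param lr,batch_size,max_epochs,patience CNN training control.
#' @param nrounds,max_depth,eta XGBoost hyperparameters.
#' @param lambda Ridge penalty for the logistic family.
#' @param cutoff Operating point on the score: call = score >= cutoff.
#' @param seed RNG seed.
#' @return An object of class `threshold_classifier_config`.
#' @export
threshold_classifier_config <- function(family = c("cnn", "xgboost",
                                                   "logistic"),
                                        channels = c(16L, 32L, 64L),
                                        kernels = c(9L, 5L, 3L),
                                        dropout = 0.25, fc_units = 64L,
                                        lr = 1e-3, batch_size = 64L,
                                        max_epochs = 80L, patience = 25L,
                                        nrounds = 150L, max_depth = 4L,
                                        eta = 0.1, lambda = 1e-2,
                                        cutoff = 0.5, seed = 1L) {
  family <- match.arg(family)
  structure(as.list(environment()), class = "threshold_classifier_config")
}

#' Train a supra/sub-threshold waveform classifier
#'
#' @param x Training matrix: one stack-scaled (and, for the `xgboost` and
#'   `logistic` families, time-warp-aligned) waveform per row.
#' @param y Binary labels: 1 = above threshold (positive class).
#' @param xval,yval Validation set (drives CNN early stopping; ignored by
#'   the other families).
#' @param weights Optional per-sample loss weights.
#' @param config A [threshold_classifier_config()].
#' @return An object of class `abr_threshold_model`.
#' @export
train_threshold_classifier <- function(x, y, xval = NULL, yval = NULL,
                                       weights = NULL,
                                       config =
                                         threshold_classifier_config()) {
  y <- as.numeric(y)
  fit <- switch(
    config$family,
    cnn = {
      if (is.null(xval)) stop("the cnn family needs a validation set")
      set.seed(config$seed)
      net <- nn_build_cnn(ncol(x), config$channels, config$kernels,
                          dropout = config$dropout,
                          fc_units = config$fc_units)
      nn_fit(net, x, y, xval, as.numeric(yval), loss = "bce",
             weights = weights, max_epochs = config$max_epochs,
             patience = config$patience, lr = config$lr,
             batch_size = config$batch_size, seed = config$seed)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
      if (!is.null(weights)) xgboost::setinfo(dtrain, "weight", weights)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = config$max_depth, eta = config$eta,
                      nthread = 1L, seed = config$seed),
        data = dtrain, nrounds = config$nrounds, verbose = 0)
    },
    logistic = {
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = config$lambda, weights = weights,
                     standardize = FALSE)
    })
  structure(list(fit = fit, family = config$family, config = config,
                 n_points = ncol(x), fitted = TRUE),
            class = "abr_threshold_model")
}

#' Score waveforms as supra-threshold responses
#'
#' @param model A fitted `abr_threshold_model`.
#' @param x A preprocessed [abr_waveform()] or a numeric matrix of
#'   preprocessed waveforms (rows), matching the model family's pipeline.
#' @return Scores in `[0, 1]`; the probability-like confidence that each
#'   waveform is above threshold. Deterministic for identical input.
#' @export
classify_waveform <- function(model, x) {
  if (!inherits(model, "abr_threshold_model") || !isTRUE(model$fitted)) {
    stop("model is not a fitted abr_threshold_model")
  }
  if (inherits(x, "abr_waveform")) x <- matrix(x$voltages, nrow = 1)
  if (ncol(x) != model$n_points) stop("input length mismatch")
  switch(model$family,
         cnn = stats::plogis(nn_predict(model$fit, x)),
         xgboost = as.numeric(stats::predict(
           model$fit, xgboost::xgb.DMatrix(x, nthread = 1L))),
         logistic = as.numeric(stats::predict(model$fit, x,
                                              type = "response")))
}

#' Stack-level hearing threshold from per-level calls
#'
#' The default (`literal`) rule returns the quietest tested level whose
#' waveform is called a hearing response. The `contiguous` rule returns the
#' quietest level of the unbroken positive run that starts at the loudest
#' level, which is robust to isolated false positives deep below threshold.
#' All-negative calls give `Inf` ("no response"); all-positive calls give
#' the quietest tested level.
#'
#' @param levels_db Tested levels (any order; sorted internally).
#' @param calls Binary calls (1 = above threshold), one per level.
#' @param rule `"literal"` (default) or `"contiguous"`.
#' @return Threshold in dB, a member of `levels_db`, or `Inf` for
#'   no-response.
#' @export
estimate_threshold <- function(levels_db, calls,
                               rule = c("literal", "contiguous")) {
  rule <- match.arg(rule)
  if (length(levels_db) == 0L) stop("empty stack")
  if (length(levels_db) != length(calls)) {
    stop("levels_db and calls must have equal length")
  }
  ord <- order(levels_db, decreasing = TRUE)
  lv <- levels_db[ord]
  cl <- as.integer(calls[ord] > 0)
  if (rule == "literal") {
    pos <- which(cl == 1L)
    if (length(pos) == 0L) return(Inf)
    return(lv[max(pos)])
  }
  # contiguous: follow the positive run from the loudest level down
  if (cl[1] == 0L) return(Inf)
  run_end <- 1L
  while (run_end < length(cl) && cl[run_end + 1L] == 1L) {
    run_end <- run_end + 1L
  }
  lv[run_end]
}

#' Estimate thresholds for a batch of stacks
#'
#' For each stack: resample to the canonical grid, scale with
#' [scale_stack()], time-warp align (for the `xgboost`/`logistic` families),
#' score every level with the classifier, call at the configured operating
#' point, and apply [estimate_threshold()]. Per-stack failures are isolated:
#' the stack is reported with an `NA` threshold and a warning, and the batch
#' continues.
#'
#' @param stacks List of [abr_stack()].
#' @param model A fitted `abr_threshold_model`.
#' @param rule Threshold rule, see [estimate_threshold()].
#' @param grid The [abr_grid()].
#' @param align Whether to time-warp align before scoring; defaults to the
#'   model family's convention (`TRUE` for `xgboost`/`logistic`, `FALSE`
#'   for `cnn`).
#' @return List of class-`abr_threshold_call` objects (fields: subject_id,
#'   frequency_khz, levels_db, scores, calls, threshold_db); see
#'   [threshold_calls_df()] for a flat summary.
#' @export
batch_thresholds <- function(stacks, model, rule = "literal",
                             grid = abr_grid(), align = NULL) {
  if (is.null(align)) align <- model$family %in% c("xgboost", "logistic")
  out <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    res <- tryCatch({
      sc <- scale_stack(abr_stack(lapply(s$waveforms, resample_to_grid,
                                         grid = grid)))
      if (align && length(sc$waveforms) > 1L) {
        sc <- align_stack(sc, grid = grid)$stack
      }
      xm <- do.call(rbind, lapply(sc$waveforms, function(w) w$voltages))
      scores <- classify_waveform(model, xm)
      calls <- as.integer(scores >= model$config$cutoff)
      list(subject_id = s$subject_id, frequency_khz = s$frequency_khz,
           levels_db = sc$levels_db, scores = scores, calls = calls,
           threshold_db = estimate_threshold(sc$levels_db, calls, rule))
    }, error = function(e) {
      warning(sprintf("stack %s|%s failed: %s", s$subject_id,
                      s$frequency_khz, conditionMessage(e)))
      list(subject_id = s$subject_id, frequency_khz = s$frequency_khz,
           levels_db = s$levels_db, scores = rep(NA_real_, length(s)),
           calls = rep(NA_integer_, length(s)), threshold_db = NA_real_)
    })
    out[[i]] <- structure(res, class = "abr_threshold_call")
  }
  out
}

#' Flatten threshold calls into a data frame
#'
#' @param calls List of `abr_threshold_call` from [batch_thresholds()].
#' @return Data frame with one row per stack: subject, frequency_khz,
#'   threshold_db (`Inf` = no response).
#' @export
threshold_calls_df <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(subject = cl$subject_id, frequency_khz = cl$frequency_khz,
               threshold_db = cl$threshold_db, stringsAsFactors = FALSE)
  }))
}

#' @export
print.abr_threshold_call <- function(x, ...) {
  thr <- if (is.infinite(x$threshold_db)) "no-response"
         else sprintf("%g dB", x$threshold_db)
  cat(sprintf("<abr_threshold_call: subject %s, %.4g kHz -> %s>\n",
              x$subject_id, x$frequency_khz, thr))
  invisible(x)
}
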