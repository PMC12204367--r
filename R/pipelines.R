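# High-level wrappers tying the modules together: synthetic data in, fitted
# models and recovery metrics out. These are what the command-line entry
# points and the reproducibility script call.

#' Train and evaluate the wave 1 peak pipeline on synthetic data
#'
#' Generates a seeded synthetic dataset, splits it by subject, trains the
#' latency regressor on the supra-threshold training waveforms, then runs
#' the full two-step detector (scaling, regression, refinement) on the
#' held-out test waveforms and measures wave 1 latency and amplitude
#' recovery against the generator's ground truth.
#'
#' @param cfg A [synth_config()]; its seed drives the whole experiment.
#' @param reg_config A [peak_regressor_config()].
#' @param snr_min Test waveforms whose true wave 1 amplitude is below
#'   `snr_min * noise_sd` are excluded from scoring (near-threshold,
#'   noise-dominated traces are reported separately in the count).
#' @param grid The canonical [abr_grid()].
#' @return List: `model`, `split`, `eval` (latency MAE/RMSE in ms, amplitude
#'   RMSE in uV, n scored), and the per-waveform `predictions` data frame.
#' @export
run_peak_pipeline <- function(cfg = synth_config(),
                              reg_config = peak_regressor_config(),
                              snr_min = 3, grid = abr_grid()) {
  ds <- generate_dataset(cfg)
  stacks <- resample_stacks(ds$stacks, grid)
  m <- stacks_to_matrix(stacks)
  tr <- ds$truth$waveforms
  stopifnot(nrow(tr) == nrow(m$x))
  xs <- t(apply(m$x, 1, scale_unit_interval))

  split <- split_by_subject(m$meta, seed = cfg$seed)
  part <- function(ids) which(m$meta$subject_id %in% ids & tr$above_threshold)
  itr <- part(split$train); iva <- part(split$val); ite <- part(split$test)

  w_tr <- source_balanced_weights(m$meta$source_label[itr])
  model <- train_peak_regressor(xs[itr, , drop = FALSE], tr$peak_idx1[itr],
                                xs[iva, , drop = FALSE], tr$peak_idx1[iva],
                                weights = w_tr, config = reg_config)

  ite <- ite[tr$wave1_amplitude_uv[ite] >= snr_min * cfg$noise_sd_uv]
  pred <- predict_wave1_index(model, xs[ite, , drop = FALSE])
  lat_pred <- numeric(length(ite)); amp_pred <- numeric(length(ite))
  for (j in seq_along(ite)) {
    i <- ite[j]
    w <- abr_waveform(m$meta$subject_id[i], m$meta$frequency_khz[i],
                      m$meta$level_db[i], m$x[i, ])
    ps <- refine_peaks(w, pred[j], grid = grid)
    lat_pred[j] <- ps$wave1_latency_ms
    amp_pred[j] <- ps$wave1_amplitude_uv
  }
  ok <- !is.na(lat_pred) & !is.na(amp_pred)
  lat_eval <- evaluate_peaks(lat_pred[ok], tr$wave1_latency_ms[ite][ok],
                             n_boot = 0L)
  amp_eval <- evaluate_peaks(amp_pred[ok], tr$wave1_amplitude_uv[ite][ok],
                             n_boot = 0L)
  list(model = model, split = split,
       eval = list(latency_mae_ms = lat_eval$mae,
                   latency_rmse_ms = lat_eval$rmse,
                   amplitude_rmse_uv = amp_eval$rmse,
                   n_scored = sum(ok), n_test = length(ite),
                   n_train = length(itr)),
       predictions = data.frame(
         subject = m$meta$subject_id[ite],
         frequency_khz = m$meta$frequency_khz[ite],
         level_db = m$meta$level_db[ite],
         pred_latency_ms = lat_pred, pred_amplitude_uv = amp_pred,
         true_latency_ms = tr$wave1_latency_ms[ite],
         true_amplitude_uv = tr$wave1_amplitude_uv[ite],
         stringsAsFactors = FALSE))
}

# Stack-scale (and optionally align) a list of stacks and return the
# feature matrix with waveform metadata.
prepare_threshold_features <- function(stacks, grid = abr_grid(),
                                       align = FALSE) {
  prepped <- lapply(stacks, function(s) {
    sc <- scale_stack(abr_stack(lapply(s$waveforms, resample_to_grid,
                                       grid = grid)))
    if (align && length(sc$waveforms) > 1L) {
      sc <- align_stack(sc, grid = grid)$stack
    }
    sc
  })
  stacks_to_matrix(prepped)
}

#' Train and evaluate the hearing-threshold pipeline on synthetic data
#'
#' Generates a seeded synthetic dataset, splits it by subject, trains a
#' supra/sub-threshold classifier of the requested family (with per-source
#' weighting and, for the CNN, one round of augmentation doubling the
#' training matrix), then estimates per-stack thresholds on held-out
#' subjects and scores them against the generator's true thresholds.
#'
#' @param cfg A [synth_config()].
#' @param clf_config A [threshold_classifier_config()].
#' @param rule Threshold rule, see [estimate_threshold()].
#' @param augment Whether to double the training matrix by augmentation
#'   (default: only for the CNN family).
#' @param eval_cfg Optional second [synth_config()]: when given, its whole
#'   simulated cohort (necessarily disjoint subjects) is the evaluation set
#'   and `cfg`'s subjects are used only for training/validation.
#' @param grid The canonical [abr_grid()].
#' @return List: `model`, `split`, `eval` (waveform-level classifier report
#'   plus stack-level within-5/10/15-dB proportions and threshold MAE) and
#'   the per-stack `calls` data frame.
#' @export
run_threshold_pipeline <- function(cfg = synth_config(),
                                   clf_config =
                                     threshold_classifier_config(),
                                   rule = "literal", augment = NULL,
                                   eval_cfg = NULL, grid = abr_grid()) {
  if (is.null(augment)) augment <- clf_config$family == "cnn"
  ds <- generate_dataset(cfg)
  align <- clf_config$family %in% c("xgboost", "logistic")
  feat <- prepare_threshold_features(ds$stacks, grid, align = align)
  tr <- ds$truth$waveforms
  stopifnot(nrow(tr) == nrow(feat$x))
  labels <- as.integer(tr$above_threshold)

  split <- split_by_subject(feat$meta, seed = cfg$seed)
  itr <- which(feat$meta$subject_id %in% split$train)
  iva <- which(feat$meta$subject_id %in% split$val)
  ite_stack <- which(vapply(ds$stacks, function(s) {
    s$subject_id %in% split$test
  }, logical(1)))

  x_tr <- feat$x[itr, , drop = FALSE]; y_tr <- labels[itr]
  w_tr <- source_balanced_weights(feat$meta$source_label[itr])
  if (augment) {
    aug <- augment_waveforms(x_tr, seed = cfg$seed)
    x_tr <- aug$x
    y_tr <- y_tr[aug$origin]
    w_tr <- source_balanced_weights(
      feat$meta$source_label[itr][aug$origin])
  }
  model <- train_threshold_classifier(
    x_tr, y_tr, feat$x[iva, , drop = FALSE], labels[iva],
    weights = w_tr, config = clf_config)

  if (is.null(eval_cfg)) {
    test_stacks <- ds$stacks[ite_stack]
    truth_thr <- ds$truth$stacks$threshold_db[ite_stack]
    ite <- which(feat$meta$stack_index %in% ite_stack)
    test_x <- feat$x[ite, , drop = FALSE]
    test_labels <- labels[ite]
  } else {
    ds_eval <- generate_dataset(eval_cfg)
    test_stacks <- ds_eval$stacks
    truth_thr <- ds_eval$truth$stacks$threshold_db
    feat_eval <- prepare_threshold_features(test_stacks, grid,
                                            align = align)
    test_x <- feat_eval$x
    test_labels <- as.integer(ds_eval$truth$waveforms$above_threshold)
  }
  calls <- batch_thresholds(test_stacks, model, rule = rule, grid = grid)
  cdf <- threshold_calls_df(calls)

  # waveform-level scores on the held-out stacks
  scores <- classify_waveform(model, test_x)
  clf_eval <- evaluate_classifier(scores, test_labels,
                                  cutoff = clf_config$cutoff, n_boot = 0L)
  finite <- is.finite(cdf$threshold_db) & is.finite(truth_thr)
  list(model = model, split = split,
       eval = list(
         classifier = clf_eval,
         within_5db = as.numeric(within_k_db(cdf$threshold_db, truth_thr, 5)),
         within_10db = as.numeric(within_k_db(cdf$threshold_db, truth_thr,
                                              10)),
         within_15db = as.numeric(within_k_db(cdf$threshold_db, truth_thr,
                                              15)),
         threshold_mae_db = if (any(finite)) {
           mean(abs(cdf$threshold_db[finite] - truth_thr[finite]))
         } else NA_real_,
         n_stacks = length(test_stacks)),
       calls = cbind(cdf, true_threshold_db = truth_thr))
}
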