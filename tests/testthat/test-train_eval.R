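test_that("subject splits honor the 80/20 and 20%-validation fractions", {
  meta <- data.frame(subject_id = paste0("m", 1:10), source_label = "A")
  sp <- split_by_subject(meta, seed = 1)
  expect_length(sp$train, 6)
  expect_length(sp$val, 2)
  expect_length(sp$test, 2)
  all_ids <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_ids, meta$subject_id)
  expect_equal(anyDuplicated(all_ids), 0)

  # reproducible under the same seed, different under another
  expect_identical(sp, split_by_subject(meta, seed = 1))
  expect_false(identical(sp, split_by_subject(meta, seed = 2)))

  # per-source independence: a 10 + 5 mixture splits source-wise
  meta2 <- data.frame(subject_id = c(paste0("a", 1:10), paste0("b", 1:5)),
                      source_label = rep(c("A", "B"), c(10, 5)))
  sp2 <- split_by_subject(meta2, seed = 3)
  for (part in sp2) {
    expect_true(length(grep("^a", part)) > 0 || length(part) < 3)
  }
  in_b <- vapply(sp2, function(p) sum(grepl("^b", p)), numeric(1))
  expect_equal(sum(in_b), 5)
  expect_true(all(in_b >= 1))      # every partition gets a source-B subject

  meta3 <- data.frame(subject_id = c("x", "y"), source_label = "A")
  expect_error(split_by_subject(meta3), "at least 3")
})

test_that("source-balanced weights equalize per-source totals", {
  lab <- rep(c("A", "B"), c(100, 300))
  w <- source_balanced_weights(lab)
  expect_equal(unique(w[lab == "A"]), 2.0)
  expect_equal(unique(w[lab == "B"]), 2 / 3)
  expect_equal(sum(w[lab == "A"]), 200)
  expect_equal(sum(w[lab == "B"]), 200)
  expect_equal(sum(w), 400)

  expect_equal(source_balanced_weights(rep("A", 7)), rep(1, 7))
  expect_equal(source_balanced_weights(rep(c("A", "B"), 5)), rep(1, 10))

  set.seed(4)
  for (i in 1:10) {
    sizes <- sample(1:50, sample(2:5, 1))
    lab <- rep(paste0("s", seq_along(sizes)), sizes)
    w <- source_balanced_weights(lab)
    sums <- tapply(w, lab, sum)
    expect_lt(max(sums) - min(sums), 1e-12)
  }
})

test_that("augmentation doubles the set, is seeded, and is identity at zero magnitude", {
  set.seed(5)
  x <- matrix(runif(50 * 244), 50, 244)
  a1 <- augment_waveforms(x, seed = 9)
  expect_equal(nrow(a1$x), 100)
  expect_equal(a1$origin, c(1:50, 1:50))
  expect_identical(a1$x, augment_waveforms(x, seed = 9)$x)
  expect_false(identical(a1$x[51:100, ], x))

  a0 <- augment_waveforms(x, noise_sd = 0, elastic_jitter = 0,
                          shift_max = 0L, seed = 9)
  expect_equal(a0$x[51:100, ], x, tolerance = 1e-9)
})

test_that("the early-stopping rule matches hand-computed halt and best epochs", {
  # strictly decreasing for 30 epochs then flat: halt at 55, best at 30
  losses <- c(seq(1, 0.5, length.out = 30), rep(0.5, 100))
  tr <- early_stopping_trace(losses, patience = 25)
  expect_equal(tr$stop_epoch, 55)
  expect_equal(tr$best_epoch, 30)
  expect_true(tr$stopped_early)

  # improvement every epoch: never halts
  tr2 <- early_stopping_trace(seq(2, 1, length.out = 40), patience = 25)
  expect_false(tr2$stopped_early)
  expect_equal(tr2$stop_epoch, 40)
  expect_equal(tr2$best_epoch, 40)

  tr3 <- early_stopping_trace(c(1.0, 0.9, 0.95), patience = 1)
  expect_equal(tr3$stop_epoch, 3)
  expect_equal(tr3$best_epoch, 2)
})

test_that("classifier metrics match oracles and handle ties and edge cases", {
  # perfectly separated scores
  r <- evaluate_classifier(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                           n_boot = 0)
  expect_equal(r$aucroc, 1.0)
  expect_equal(r$aucpr, 1.0)
  expect_equal(r$accuracy, 1.0)

  # spec'd concordance example
  r2 <- evaluate_classifier(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0),
                            n_boot = 0)
  expect_equal(r2$aucroc, 0.75, tolerance = 1e-12)

  # all-tied scores: half credit per pair
  r3 <- evaluate_classifier(rep(0.5, 10), rep(c(0, 1), 5), n_boot = 0)
  expect_equal(r3$aucroc, 0.5, tolerance = 1e-12)

  # single-class labels: AUCs undefined
  r4 <- evaluate_classifier(runif(5), rep(1, 5), n_boot = 0)
  expect_true(is.na(r4$aucroc))

  # tnr is the complement of fpr; bootstrap CIs bracket the point estimate
  set.seed(6)
  sc <- runif(80); lb <- rbinom(80, 1, 0.5)
  r5 <- evaluate_classifier(sc, lb, n_boot = 200, seed = 2)
  expect_equal(r5$tnr, 1 - r5$fpr)
  auc_ci <- r5$ci[r5$ci$metric == "aucroc", ]
  expect_true(auc_ci$lower <= r5$aucroc && r5$aucroc <= auc_ci$upper)
})

test_that("trapezoidal AUCROC equals pairwise concordance on random instances", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    # coarse score grid so ties actually occur
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0 || sum(lb) == n) next
    expect_equal(evaluate_classifier(sc, lb, n_boot = 0)$aucroc,
                 brute_concordance_auc(sc, lb), tolerance = 1e-12)
  }
  # cross-check against an independent ROC implementation
  set.seed(8)
  sc <- runif(150); lb <- rbinom(150, 1, 0.5)
  expect_equal(evaluate_classifier(sc, lb, n_boot = 0)$aucroc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-9)
})

test_that("peak-error summaries reduce to their defining formulas", {
  r <- evaluate_peaks(c(1, 2, 3), c(1, 2, 3), n_boot = 0)
  expect_equal(r$rmse, 0)
  expect_equal(r$mae, 0)

  r2 <- evaluate_peaks(c(1.1, 0.9), c(1, 1), n_boot = 0)
  expect_equal(r2$mae, 0.1)
  expect_equal(r2$mean_error, 0)
  expect_equal(r2$rmse, 0.1)

  set.seed(9)
  p <- rnorm(40); t <- rnorm(40)
  r3 <- evaluate_peaks(p, t, n_boot = 0)
  expect_equal(r3$rmse, sqrt(mean((p - t)^2)), tolerance = 1e-12)
  expect_equal(r3$mae, mean(abs(p - t)), tolerance = 1e-12)
  expect_equal(r3$sem, sd(p - t) / sqrt(40), tolerance = 1e-12)
  expect_error(evaluate_peaks(1:3, 1:4), "mismatch")
})

test_that("within-k-dB agreement counts no-response pairs sensibly", {
  expect_equal(as.numeric(within_k_db(c(40, 50), c(40, 50), 5)), 1)
  expect_equal(as.numeric(within_k_db(c(40, 45, 50, 60),
                                      c(40, 40, 40, 40), 5)), 0.5)
  expect_equal(as.numeric(within_k_db(c(40, 60), c(40, 40), 100)), 1)
  # both no-response: hit; one-sided no-response: miss
  expect_equal(as.numeric(within_k_db(c(Inf, Inf), c(Inf, 40), 10)), 0.5)
  expect_equal(attr(within_k_db(c(Inf, Inf), c(Inf, 40), 10),
                    "n_noresponse"), 2)
})

test_that("proportion comparisons match the pooled z-test by hand", {
  r <- compare_proportions(80, 100, 80, 100)
  expect_equal(r$difference, 0)
  expect_equal(r$p_value, 1)

  r2 <- compare_proportions(90, 100, 80, 100)
  pool <- 170 / 200
  z_hand <- (0.9 - 0.8) / sqrt(pool * (1 - pool) * (1 / 100 + 1 / 100))
  expect_equal(r2$z, z_hand, tolerance = 1e-12)
  expect_equal(r2$p_value, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)

  # Bonferroni multiplies and caps
  r3 <- compare_proportions(90, 100, 80, 100, bonferroni_m = 6)
  expect_equal(r3$p_value, min(1, 6 * r2$p_value))
  r4 <- compare_proportions(55, 100, 50, 100, bonferroni_m = 6)
  expect_equal(r4$p_value, 1)

  # degenerate equal proportions collapse the CI
  r5 <- compare_proportions(100, 100, 100, 100)
  expect_equal(r5$ci, c(0, 0))
  expect_equal(r5$p_value, 1)
})
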