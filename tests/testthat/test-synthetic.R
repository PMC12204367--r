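test_that("dataset dimensions and determinism follow the configuration", {
  cfg <- synth_config(n_subjects = 2, frequencies_khz = c(8, 16),
                      levels_db = seq(90, 10, by = -10), seed = 3)
  ds <- generate_dataset(cfg)
  expect_length(ds$stacks, 4)
  expect_equal(sum(vapply(ds$stacks, length, integer(1))), 36)
  expect_equal(nrow(ds$truth$waveforms), 36)
  expect_equal(nrow(ds$truth$stacks), 4)

  ds2 <- generate_dataset(cfg)
  expect_identical(lapply(ds$stacks, function(s) {
    lapply(s$waveforms, function(w) w$voltages)
  }), lapply(ds2$stacks, function(s) {
    lapply(s$waveforms, function(w) w$voltages)
  }))

  cfg2 <- synth_config(n_subjects = 2, frequencies_khz = c(8, 16),
                       levels_db = seq(90, 10, by = -10), seed = 4)
  ds3 <- generate_dataset(cfg2)
  expect_false(identical(ds$stacks[[1]]$waveforms[[1]]$voltages,
                         ds3$stacks[[1]]$waveforms[[1]]$voltages))
})

test_that("noise-free waveforms peak where the truth record says", {
  gw <- make_clean_waveform(level = 85, threshold = 40)
  g <- abr_grid()
  p1 <- gw$truth$peak_idx1
  win <- (p1 - 7):(p1 + 7) + 1
  expect_equal(win[which.max(gw$waveform$voltages[win])] - 1, p1)
  expect_true(all(diff(unlist(gw$truth[paste0("peak_idx", 1:5)])) > 0))
  # troughs follow their peaks
  expect_true(all(unlist(gw$truth[paste0("trough_idx", 1:5)]) >
                    unlist(gw$truth[paste0("peak_idx", 1:5)])))

  # below threshold with no noise: silence
  gw2 <- generate_waveform(synth_config(noise_sd_uv = 0), "s", 16, 20, 40,
                           noise = FALSE)
  expect_equal(max(abs(gw2$waveform$voltages)), 0, tolerance = 1e-6)
  expect_false(gw2$truth$above_threshold)
})

test_that("amplitudes grow with level and latencies shorten", {
  cfg <- synth_config(n_subjects = 25, frequencies_khz = 16,
                      noise_sd_uv = 0, seed = 7)
  ds <- generate_dataset(cfg)
  tr <- ds$truth$waveforms
  st <- ds$truth$stacks
  amp_at <- function(offset) {
    vapply(seq_len(nrow(st)), function(i) {
      lev <- st$threshold_db[i] + offset
      j <- tr$subject == st$subject[i] & tr$level_db == lev
      if (!any(j)) NA_real_ else tr$wave1_amplitude_uv[j]
    }, numeric(1))
  }
  a40 <- amp_at(40); a10 <- amp_at(10)
  ok <- !is.na(a40) & !is.na(a10)
  expect_gt(mean(a40[ok]), mean(a10[ok]))

  # latency is non-increasing in level within each stack
  for (i in seq_len(nrow(st))) {
    j <- tr$subject == st$subject[i] & tr$above_threshold
    sub <- tr[j, ]
    sub <- sub[order(sub$level_db, decreasing = TRUE), ]
    expect_true(all(diff(sub$wave1_latency_ms) >= 0))
  }
})

test_that("sub-threshold waveforms are pure recording noise at the set sd", {
  cfg <- synth_config(n_subjects = 8, frequencies_khz = c(8, 16),
                      levels_db = seq(90, 10, by = -5),
                      noise_sd_uv = 0.2, seed = 11)
  ds <- generate_dataset(cfg)
  tr <- ds$truth$waveforms
  m <- stacks_to_matrix(ds$stacks)
  sub <- which(!tr$above_threshold)
  expect_gt(length(sub), 100)
  rms <- sqrt(mean(m$x[sub, ]^2))
  expect_equal(rms, 0.2, tolerance = 0.1 * 0.2)
})

test_that("multi-rate sources exercise resampling and keep their labels", {
  cfg <- synth_config(n_subjects = 4, frequencies_khz = 16,
                      sources = c(labA = 244L, labB = 488L), seed = 2)
  ds <- generate_dataset(cfg)
  lens <- vapply(ds$stacks, function(s) length(s$waveforms[[1]]$voltages),
                 integer(1))
  expect_setequal(unique(lens), c(244L, 488L))
  labs <- vapply(ds$stacks, function(s) s$waveforms[[1]]$source_label,
                 character(1))
  expect_setequal(unique(labs), c("labA", "labB"))
  rs <- resample_stacks(ds$stacks)
  expect_true(all(vapply(rs, function(s) {
    all(lengths(lapply(s$waveforms, function(w) w$voltages)) == 244L)
  }, logical(1))))
})
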