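write_wide_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

wide_df <- function(subject, freq, level, volts) {
  out <- data.frame(subject = subject, frequency_khz = freq,
                    level_db = level, stringsAsFactors = FALSE)
  vm <- do.call(rbind, volts)
  colnames(vm) <- paste0("t", seq_len(ncol(vm)) - 1)
  cbind(out, vm)
}

test_that("wide CSV rows are grouped into level-sorted stacks", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- wide_df("m1", 16, c(60, 80, 40),
                list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(9, 10, 11, 12)))
  write_wide_csv(df, f)
  stacks <- read_abr_csv(f)
  expect_length(stacks, 1)
  expect_equal(stacks[[1]]$levels_db, c(80, 60, 40))
  expect_equal(stacks[[1]]$waveforms[[1]]$voltages, c(5, 6, 7, 8))
  expect_equal(stacks[[1]]$waveforms[[3]]$voltages, c(9, 10, 11, 12))

  # two subjects partition into two stacks of three; no row lost
  f2 <- withr::local_tempfile(fileext = ".csv")
  df2 <- wide_df(rep(c("m1", "m2"), each = 3), 16,
                 rep(c(80, 60, 40), 2),
                 replicate(6, rnorm(4), simplify = FALSE))
  write_wide_csv(df2, f2)
  st2 <- read_abr_csv(f2)
  expect_length(st2, 2)
  expect_equal(sum(vapply(st2, length, integer(1))), 6)
})

test_that("wide CSV reader rejects malformed input with specific errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- wide_df("m1", 16, 80, list(c(1, 2, 3, 4)))
  names(df)[2] <- "freq"
  write_wide_csv(df, f)
  expect_error(read_abr_csv(f), "frequency_khz")

  f2 <- withr::local_tempfile(fileext = ".csv")
  df2 <- wide_df("m1", 16, c(80, 80), list(1:4, 5:8))
  write_wide_csv(df2, f2)
  expect_error(read_abr_csv(f2), "duplicate")

  f3 <- withr::local_tempfile(fileext = ".csv")
  df3 <- wide_df("m1", 16, c(80, 60), list(1:4, 5:8))
  df3$t2[2] <- "oops"
  write_wide_csv(df3, f3)
  expect_error(read_abr_csv(f3), "row 2")
})

test_that("volt-unit input is converted to microvolts on ingest", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_wide_csv(wide_df("m1", 16, 80, list(c(1e-6, 2e-6, 3e-6, 4e-6))), f)
  stacks <- read_abr_csv(f, unit = "V")
  expect_equal(stacks[[1]]$waveforms[[1]]$voltages, c(1, 2, 3, 4))
})

test_that("long TSV reader keeps native time grids and checks monotonicity", {
  f <- withr::local_tempfile(fileext = ".tsv")
  n <- 244
  tms <- (seq_len(n) - 1) * (10 / n)
  df <- data.frame(
    subject = "m1", frequency_khz = 8,
    level_db = rep(c(80, 60), each = n),
    time_ms = rep(tms, 2), voltage_uv = rnorm(2 * n))
  utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  stacks <- read_abr_tsv(f)
  expect_length(stacks, 1)
  expect_length(stacks[[1]]$waveforms, 2)
  expect_length(stacks[[1]]$waveforms[[1]]$voltages, n)
  expect_equal(stacks[[1]]$waveforms[[1]]$times_ms, tms)

  # non-monotone time within a group is an error naming the key
  f2 <- withr::local_tempfile(fileext = ".tsv")
  df2 <- data.frame(subject = "m1", frequency_khz = 8, level_db = 80,
                    time_ms = c(0, 0.05, 0.04), voltage_uv = c(1, 2, 3))
  utils::write.table(df2, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_abr_tsv(f2), "m1")

  # header-only file: empty collection, not an error
  f3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df2[0, ], f3, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_length(read_abr_tsv(f3), 0)
})

test_that("metrics CSV round-trips numeric fields and the NR sentinel", {
  rows <- data.frame(
    subject = c("m2", "m1", "m1"), frequency_khz = c(8, 16, 8),
    level_db = c(80, 70, 60),
    wave1_amplitude_uv = c(1.234567, 0.333333, NA),
    wave1_latency_ms = c(1.515152, 1.842105, NA),
    threshold_db = c(40, Inf, 35))
  f <- withr::local_tempfile(fileext = ".csv")
  written <- write_metrics_csv(rows, f)
  # sorted by subject, frequency ascending, level descending
  expect_equal(written$subject, c("m1", "m1", "m2"))
  expect_equal(written$frequency_khz, c(8, 16, 8))
  lines <- readLines(f)
  expect_length(lines, 4)
  expect_match(lines[1], "^subject,frequency_khz,level_db")
  expect_true(any(grepl(",NR$", lines)))

  back <- read_metrics_csv(f)
  expect_equal(back$wave1_amplitude_uv, written$wave1_amplitude_uv,
               tolerance = 1e-6)
  expect_equal(back$wave1_latency_ms, written$wave1_latency_ms,
               tolerance = 1e-6)
  expect_equal(back$threshold_db, written$threshold_db)

  # empty collection: header-only file
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(rows[0, ], f2)
  expect_length(readLines(f2), 1)
})

test_that("stack constructor enforces shared identity and unique levels", {
  w <- function(s, l) abr_waveform(s, 16, l, rnorm(8))
  expect_error(abr_stack(list(w("a", 80), w("b", 70))), "share")
  expect_error(abr_stack(list(w("a", 80), w("a", 80))), "duplicate")
  s <- abr_stack(list(w("a", 60), w("a", 80)))
  expect_equal(s$levels_db, c(80, 60))
})
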