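test_that("resampling is the identity at the grid length and exact on lines", {
  g <- abr_grid()
  v <- rnorm(244)
  w <- abr_waveform("s", 16, 80, v)
  expect_identical(resample_to_grid(w, g)$voltages, v)

  # downsampling branch (linear) reproduces linear data exactly
  t488 <- (0:487) * (10 / 488)
  w2 <- abr_waveform("s", 16, 80, 2 * t488, times_ms = t488)
  out2 <- resample_to_grid(w2, g)
  expect_equal(out2$voltages, 2 * grid_times(g), tolerance = 1e-12)

  # upsampling branch (natural cubic spline) reproduces lines exactly
  t122 <- (0:121) * (10 / 122)
  w3 <- abr_waveform("s", 16, 80, 3 + 0.5 * t122, times_ms = t122)
  out3 <- resample_to_grid(w3, g)
  expect_equal(out3$voltages, 3 + 0.5 * grid_times(g), tolerance = 1e-9)

  expect_error(resample_to_grid(abr_waveform("s", 16, 80, 1:3)), "4")
})

test_that("resampling matches independent interpolation oracles", {
  g <- abr_grid()
  tg <- grid_times(g)
  # downsampling vs a two-point linear oracle
  t300 <- (0:299) * (10 / 300)
  v300 <- sin(2 * pi * t300 / 3) + 0.3 * cos(2 * pi * t300 / 0.9)
  w <- abr_waveform("s", 16, 80, v300, times_ms = t300)
  expect_equal(resample_to_grid(w, g)$voltages,
               brute_linear_interp(t300, v300, tg), tolerance = 1e-9)

  # upsampling vs an independent natural-spline solve
  t61 <- (0:60) * (10 / 61)
  v61 <- sin(2 * pi * t61 / 2.5)
  w2 <- abr_waveform("s", 16, 80, v61, times_ms = t61)
  expect_equal(resample_to_grid(w2, g)$voltages,
               brute_natural_spline(t61, v61, tg), tolerance = 1e-9)

  # samples beyond the window are dropped before interpolating
  t_long <- (0:599) * (12 / 600)
  v_long <- t_long
  w3 <- abr_waveform("s", 16, 80, v_long, times_ms = t_long)
  out3 <- resample_to_grid(w3, g)
  expect_equal(out3$voltages, tg, tolerance = 1e-12)
})

test_that("scaling maps to [0,1], is affine-invariant, and handles constants", {
  w <- abr_waveform("s", 16, 80, c(0, 1, 2))
  expect_equal(scale_waveform(w)$voltages, c(0, 0.5, 1))

  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(50)
    sv <- scale_waveform(abr_waveform("s", 16, 80, v))$voltages
    expect_equal(min(sv), 0)
    expect_equal(max(sv), 1)
    expect_equal(order(v), order(sv))
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    sv2 <- scale_waveform(abr_waveform("s", 16, 80, a * v + b))$voltages
    expect_equal(sv, sv2, tolerance = 1e-12)
  }

  expect_warning(out <- scale_waveform(abr_waveform("s", 16, 80, rep(2, 9))),
                 "constant")
  expect_equal(out$voltages, rep(0.5, 9))
})

test_that("stack scaling pools one affine map over all members", {
  s <- abr_stack(list(abr_waveform("a", 16, 80, c(0, 1, 2, 3)),
                      abr_waveform("a", 16, 60, c(2, 3, 4, 5))))
  sc <- scale_stack(s)
  pooled <- unlist(lapply(sc$waveforms, function(w) w$voltages))
  expect_equal(min(pooled), 0)
  expect_equal(max(pooled), 1)
  # the offset ordering between the two waveforms is preserved
  expect_true(all(sc$waveforms[[1]]$voltages[1:4] <
                    sc$waveforms[[2]]$voltages[1:4] + 1e-12))
  # linearity: equally spaced input stays equally spaced
  expect_equal(diff(sc$waveforms[[1]]$voltages),
               rep(1 / 5, 3), tolerance = 1e-12)

  # a one-waveform stack reduces to per-waveform scaling
  v <- rnorm(30)
  s1 <- abr_stack(list(abr_waveform("a", 16, 80, v)))
  expect_equal(scale_stack(s1)$waveforms[[1]]$voltages,
               scale_waveform(abr_waveform("a", 16, 80, v))$voltages,
               tolerance = 1e-12)

  # pooled z-scores have mean 0 before the min-max step
  set.seed(2)
  vs <- replicate(4, rnorm(25), simplify = FALSE)
  pooled_v <- unlist(vs)
  z <- (pooled_v - mean(pooled_v)) / sd(pooled_v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
})

test_that("Gaussian smoothing matches closed form and brute-force oracle", {
  cfg <- smoothing_config(1.0)
  expect_equal(gaussian_smooth(rep(3.7, 40), cfg), rep(3.7, 40))

  # impulse response equals the normalized truncated kernel
  v <- rep(0, 41); v[21] <- 1
  sm <- gaussian_smooth(v, cfg)
  k <- exp(-((-4):4)^2 / 2); k <- k / sum(k)
  expect_equal(sm[17:25], k, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(60)
    sm <- gaussian_smooth(x, cfg)
    expect_equal(sm, brute_gaussian_smooth(x, 1, 4), tolerance = 1e-12)
    expect_lte(var(sm), var(x))
    # commutes with constant offsets
    expect_equal(gaussian_smooth(x + 5, cfg), sm + 5, tolerance = 1e-12)
  }
})
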