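test_that("a single mean shift is located within one bin and classified rising", {
  x <- c(rep(0, 49), rep(5, 51))
  cp <- changepoints_mean(x)
  expect_equal(nrow(cp), 1)
  expect_lte(abs(cp$index - 50), 1)
  expect_equal(cp$direction, "rising")

  expect_equal(nrow(changepoints_mean(rep(2, 100))), 0)
  expect_error(changepoints_mean(1:5), ">= 10 bins")
})

test_that("boxcar segmentation matches the exhaustive two-changepoint oracle", {
  x <- c(rep(0, 39), rep(6, 30), rep(0, 31))
  pen <- 2 * log(length(x)) * var(x)
  cp <- changepoints_mean(x)
  oracle <- exhaustive_cp2_oracle(x, pen)
  expect_equal(cp$index, oracle)
  expect_equal(cp$direction, c("rising", "falling"))
})

test_that("segmentation agrees with the exhaustive oracle on noisy planted shifts", {
  set.seed(101)
  n_match <- 0
  n_cases <- 60
  for (case in seq_len(n_cases)) {
    n <- sample(60:200, 1)
    k <- sample(0:2, 1)
    bounds <- sort(sample(seq(15, n - 15), k))
    means <- cumsum(c(runif(1, 0, 2), runif(k, 1.5, 4) * sample(c(-1, 1), k, TRUE)))
    x <- rep(means, diff(c(0, bounds, n))) + rnorm(n, 0, 0.3)
    pen <- 2 * log(n) * var(x)
    got <- changepoints_mean(x)$index
    want <- exhaustive_cp2_oracle(x, pen)
    ok <- length(got) == length(want) &&
      (length(got) == 0 || all(abs(got - want) <= 1))
    n_match <- n_match + ok
  }
  expect_gte(n_match / n_cases, 0.95)
})

test_that("Gaussian fit recovers exact and noisy parameters", {
  t <- seq(5, 15, by = 0.1)
  y <- 6 * exp(-(t - 10)^2 / (2 * 1.5^2))
  fit <- fit_gaussian(t, y)
  expect_equal(unname(fit["amplitude"]), 6, tolerance = 1e-6)
  expect_equal(unname(fit["mean"]), 10, tolerance = 1e-6)
  expect_equal(unname(fit["sigma"]), 1.5, tolerance = 1e-6)

  set.seed(4)
  yn <- y + rnorm(length(y), 0, 0.2)
  fitn <- fit_gaussian(t, yn)
  oracle <- grid_gauss_oracle(t, yn, seq(8, 12, 0.01), seq(0.5, 3, 0.05))
  expect_equal(unname(fitn["mean"]), unname(oracle["mu"]), tolerance = 0.05)
  expect_equal(unname(fitn["mean"]), 10, tolerance = 0.2)

  expect_error(fit_gaussian(t, rep(0, length(t))), "all-zero")
  expect_error(fit_gaussian(1:3, c(0, 1, 0)), "too short")
})

test_that("a clean probe bout is detected at its center", {
  licks <- gaussian_envelope_licks(center = 10, sd = 1.2, peak_rate = 7)
  pk <- detect_peak(licks)
  expect_false(is.null(pk))
  expect_equal(pk$peak_time, 10, tolerance = 0.2)
  expect_lt(pk$start, pk$peak_time)
  expect_gt(pk$end, pk$peak_time)
  expect_gte(pk$end - pk$start, 2)
})

test_that("validity rules reject flat and too-short responses", {
  # flat 1 Hz background only: 3 Hz criterion fails on all 6 attempts
  expect_null(detect_peak(seq(0.5, 25, by = 1)))
  # 1.5-s bout at 6 Hz: duration criterion fails
  expect_null(detect_peak(seq(9, 10.4, by = 1 / 6)))
})

test_that("the duration threshold is sharp at 2 s", {
  # unsmoothed boxcar bouts with exact bin-edge boundaries
  short <- seq(8.001, 9.9, by = 1 / 8)    # spans 1.9 s of bins
  long <- seq(8.001, 10.4, by = 1 / 8)    # spans 2.4 s of bins
  expect_null(detect_peak(short, smoothing_sd = 0, max_shifts = 0))
  pk <- detect_peak(long, smoothing_sd = 0, max_shifts = 0)
  expect_false(is.null(pk))
})

test_that("window shifting rescues peaks near the window edge", {
  # bout whose falling flank lies beyond the initial 0-20 s window: the
  # first attempt finds no falling changepoint, a shifted window succeeds
  licks <- gaussian_envelope_licks(center = 20.4, sd = 0.8, peak_rate = 7,
                                   span = c(14, 26))
  pk <- detect_peak(licks)
  expect_false(is.null(pk))
  expect_gt(pk$n_window_shifts_used, 0)
  expect_equal(pk$peak_time, 20.4, tolerance = 0.02)
})

test_that("detection is translation-equivariant", {
  licks <- gaussian_envelope_licks(center = 9.4, sd = 1.1, peak_rate = 6)
  pk0 <- detect_peak(licks, align_time = 0)
  for (delta in c(-3.2, 7.7, 100)) {
    pkd <- detect_peak(licks + delta, align_time = delta)
    expect_equal(pkd$peak_time, pk0$peak_time, tolerance = 1e-9)
    expect_equal(pkd$start, pk0$start, tolerance = 1e-9)
  }
})

test_that("mean detected peak time converges to the generator center", {
  tt <- mk_probe_trials(200)
  b <- simulate_licking(tt, lick_model_params(peak_center_sd = 1, seed = 1),
                        stim_effect_params())
  pk <- detect_session_peaks(b, window_start = 0)
  expect_gt(sum(pk$valid), 150)
  expect_lt(abs(mean(pk$peak_time[pk$valid]) - 10), 0.3)
})

test_that("session peak statistics match direct computation", {
  licks <- gaussian_envelope_licks(10, 1.2, 7)
  pk <- detect_peak(licks)
  peaks <- data.frame(trial_id = 1L, align_time = 0, laser = FALSE,
                      window_start = 0, start = pk$start, end = pk$end,
                      peak_time = pk$peak_time, amplitude = pk$amplitude,
                      sigma = pk$sigma, n_window_shifts_used = 0L,
                      valid = TRUE)
  st <- peak_stats(peaks, lick_train(licks))
  expect_equal(st$mean_width, pk$end - pk$start)
  expect_equal(st$n_trials_used, 1)
  # symmetric lick distribution about the center: skewness ~ 0
  expect_lt(abs(st$skewness), 0.15)

  # right-tailed pool matches the direct moment formula
  pool <- licks[licks >= pk$start & licks <= pk$end]
  pool <- c(pool, pk$peak_time + c(2.5, 3, 3.5))  # inject a right tail
  m <- mean(pool); m2 <- mean((pool - m)^2); m3 <- mean((pool - m)^3)
  peaks2 <- peaks; peaks2$end <- pk$peak_time + 4
  st2 <- peak_stats(peaks2, lick_train(sort(pool)))
  expect_equal(st2$skewness, m3 / m2^1.5, tolerance = 0.05)
  expect_gt(st2$skewness, 0)

  expect_error(peak_stats(peaks[peaks$valid == FALSE, ], licks), "no valid")
})

test_that("peak shift is the laser minus no-laser mean peak time", {
  licks <- gaussian_envelope_licks(10, 1.2, 7)
  base <- data.frame(trial_id = 1:4, align_time = 0, laser = c(TRUE, TRUE, FALSE, FALSE),
                     window_start = 0, start = 8, end = 12,
                     peak_time = c(10, 10, 10, 10), amplitude = 6, sigma = 1.2,
                     n_window_shifts_used = 0L, valid = TRUE)
  expect_equal(peak_stats(base, lick_train(licks))$peak_shift, 0)
  shifted <- base
  shifted$peak_time[shifted$laser] <- 15
  expect_equal(peak_stats(shifted, lick_train(licks))$peak_shift, 5)
})

test_that("clock-reset sessions show the injected peak shift", {
  tt <- mk_probe_trials(100, laser_onset = 5, every_other = TRUE)
  b <- simulate_licking(tt, lick_model_params(peak_center_sd = 1, seed = 33),
                        stim_effect_params("none", timing_mode = "reset"))
  curve <- peak_shift_curve(b)
  expect_equal(nrow(curve), 1)
  expect_equal(curve$stim_onset, 5)
  expect_lt(abs(curve$shift - 5), 0.3)
})
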