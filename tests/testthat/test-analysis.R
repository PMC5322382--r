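slice <- make_slice()

test_that("baseline statistics use the n-1 sample SD", {
  tr <- force_trace(rep(7, 64), 32, "left_foot")
  bs <- baseline_stats(tr, c(0, 1))
  expect_equal(bs$mean, 7)
  expect_equal(bs$sd, 0)

  tr <- force_trace(c(1, 2, 3, 4, 5), 1, "left_foot")
  bs <- baseline_stats(tr, c(0, 5))
  expect_equal(bs$mean, 3)
  expect_equal(bs$sd, 1.5811, tolerance = 1e-4)  # sqrt(2.5)

  expect_error(baseline_stats(tr, c(10, 12)), "outside")
  expect_error(baseline_stats(force_trace(1:100, 32, "touch"), c(0, 0.1)),
               "fewer than 5")
})

test_that("threshold crossing detection matches a brute-force scan", {
  # step function crossing at a known sample
  x <- c(rep(0, 50), rep(10, 50))
  tr <- force_trace(x, 100, "f_ml")
  t_on <- detect_crossing(tr, c(0, 1), mean = 0, sd = 1, k_sd = 2,
                          direction = "above", hold = 1)
  expect_equal(t_on, 0.50)  # sample 51 at 100 Hz

  # never crossing: absence is a value
  expect_true(is.na(detect_crossing(tr, c(0, 0.4), 0, 1, 2, "above", 1)))

  # single-sample spike is debounced by a 3-sample hold
  spike <- rep(0, 100); spike[30] <- 10
  trs <- force_trace(spike, 100, "f_ml")
  expect_false(is.na(detect_crossing(trs, c(0, 1), 0, 1, 2, "above", 1)))
  expect_true(is.na(detect_crossing(trs, c(0, 1), 0, 1, 2, "above", 3)))

  # brute-force equivalence over random traces, windows and holds
  set.seed(202)
  for (i in 1:50) {
    tr <- force_trace(rnorm(200), 50, "f_ml", t0 = runif(1, -2, 2))
    w <- sort(tr$t0 + runif(2, 0, 4))
    hold <- sample(1:4, 1)
    dir <- sample(c("above", "below"), 1)
    got <- detect_crossing(tr, w, 0, 1, 1.5, dir, hold)
    want <- brute_crossing_time(tr, w, 0, 1, 1.5, dir, hold)
    expect_identical(got, want)
  }
})

test_that("detection is translation-equivariant", {
  set.seed(7)
  x <- cumsum(rnorm(300))
  for (dt in c(-3.2, 0.5, 11.07)) {
    a <- detect_crossing(force_trace(x, 100, "f_ml", t0 = 0),
                         c(0, 3), 0, 1, 2, "above", 3)
    b <- detect_crossing(force_trace(x, 100, "f_ml", t0 = dt),
                         c(dt, 3 + dt), 0, 1, 2, "above", 3)
    expect_equal(b, a + dt, tolerance = 1e-12)
  }
})

test_that("the zero-phase Butterworth filter has the expected response", {
  # DC unchanged
  dc <- marker_trace(rep(5, 400), 200)
  expect_equal(lowpass_filter(dc, 10)$samples, dc$samples, tolerance = 1e-9)

  # 50 Hz attenuated by > 20 dB at a 10 Hz cutoff
  t <- (0:1999) / 200
  s50 <- marker_trace(sin(2 * pi * 50 * t), 200)
  out <- lowpass_filter(s50, 10)
  mid <- 500:1500
  expect_lt(max(abs(out$samples[mid])), 0.1)

  # 1 Hz preserved within 1 %
  s1 <- marker_trace(sin(2 * pi * 1 * t), 200)
  out <- lowpass_filter(s1, 10)
  expect_equal(max(abs(out$samples[mid])), 1, tolerance = 0.01)

  expect_error(lowpass_filter(s1, 100), "Nyquist")
})

test_that("step-task APA amplitude is normalized by foot length", {
  p <- step_trial_params(noise_sd_force = 0, noise_sd_marker = 0,
                         fml_amplitude = 20)
  rec <- simulate_step_trial(p, slice, seed = 5)
  res <- analyze_step_recording(rec, foot_length_cm = 25)
  expect_true(res$valid)
  expect_equal(res$fml_amplitude_norm, 0.80, tolerance = 0.02)
  expect_lt(res$apa_onset, res$step_onset)

  # matched-seed suppression halves the amplitude
  ps <- step_trial_params(noise_sd_force = 0, noise_sd_marker = 0,
                          fml_amplitude = 20, condition = "supported",
                          suppression_factor = 0.5)
  rec2 <- simulate_step_trial(ps, slice, seed = 5)
  res2 <- analyze_step_recording(rec2, foot_length_cm = 25)
  expect_equal(res2$fml_amplitude_norm / res$fml_amplitude_norm, 0.5,
               tolerance = 0.02)

  expect_error(analyze_step_recording(rec, foot_length_cm = 0), "positive")
})

test_that("force magnitude is an integral ratio with the right identities", {
  tr <- force_trace(rep(4, 101), 10, "left_foot")  # constant on [0, 10.1)

  # degenerate: numerator window equals the whole window
  expect_equal(force_magnitude_pct(tr, c(0, 10), c(0, 10)), 100)

  # constant force, sub-window 10 % of the trial span
  expect_equal(force_magnitude_pct(tr, c(2, 3), c(0, 10)), 10,
               tolerance = 1e-9)

  expect_error(force_magnitude_pct(force_trace(rep(0, 50), 10, "left_foot"),
                                   c(0, 1), c(0, 5)), "not positive")
})

test_that("scanner APA quantification flags undetectable trials", {
  # fully suppressed: no APA onset exists
  p <- supine_trial_params(condition = "supported", suppression_factor = 1)
  rec <- simulate_supine_trial(p, slice, seed = 8)
  res <- analyze_supine_recording(rec)
  expect_false(res$valid)
  expect_match(res$reason, "no APA onset")
  expect_true(is.na(res$force_magnitude_pct))

  # intact trial: magnitude within bounds, onsets ordered
  rec <- simulate_supine_trial(supine_trial_params(), slice, seed = 8)
  res <- analyze_supine_recording(rec)
  expect_true(res$valid)
  expect_lt(res$apa_onset, res$leglift_onset)
  expect_gte(res$force_magnitude_pct, 0)
  expect_lte(res$force_magnitude_pct, 100)
})
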