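slice <- make_slice()

test_that("noiseless supine trials are analytically checkable", {
  # full suppression, supported: no APA, left trace flat at baseline
  p <- supine_trial_params(noise_sd = 0, condition = "supported",
                           suppression_factor = 1)
  rec <- simulate_supine_trial(p, slice, seed = 1)
  left <- rec$traces$left_foot$samples
  expect_equal(max(abs(left - p$baseline_left)), 0)

  # unsupported: the noiseless peak equals the amplitude parameter
  p <- supine_trial_params(noise_sd = 0, apa_amplitude = 5)
  rec <- simulate_supine_trial(p, slice, seed = 1)
  expect_equal(max(rec$traces$left_foot$samples) - p$baseline_left, 5,
               tolerance = 1e-9)

  # the right-foot drop equals the drop fraction
  right <- rec$traces$right_foot$samples
  expect_equal(min(right), p$baseline_right * (1 - p$lift_drop_fraction),
               tolerance = 1e-9)

  # the touch channel fires at lift onset + travel delay
  gt <- rec$ground_truth
  touch_t <- trace_times(rec$traces$touch)[which(rec$traces$touch$samples > 0)[1]]
  expect_gte(touch_t, gt$true_lift_onset + p$touch_delay)
  expect_lt(touch_t, gt$true_lift_onset + p$touch_delay + 1 / p$rate_hz)

  # ground-truth onsets respect the configured lead and latency range
  expect_equal(gt$true_lift_onset - gt$true_apa_onset, p$apa_lead)
  expect_gte(gt$true_apa_onset - slice$go_onset, p$latency_range[1])
  expect_lte(gt$true_apa_onset - slice$go_onset, p$latency_range[2])
})

test_that("an undetectably short APA lead is rejected", {
  p <- supine_trial_params(apa_lead = 0.03)  # < 2 samples at 32 Hz
  expect_error(simulate_supine_trial(p, slice), "2 sample periods")
})

test_that("simulated trials are reproducible under a fixed seed", {
  p <- supine_trial_params()
  a <- simulate_supine_trial(p, slice, seed = 9)
  b <- simulate_supine_trial(p, slice, seed = 9)
  expect_identical(a$traces$left_foot$samples, b$traces$left_foot$samples)
  expect_identical(a$ground_truth, b$ground_truth)

  ps <- step_trial_params()
  a <- simulate_step_trial(ps, slice, seed = 9)
  b <- simulate_step_trial(ps, slice, seed = 9)
  expect_identical(a$traces$f_ml$samples, b$traces$f_ml$samples)
})

test_that("step-task APA peak scales linearly with suppression", {
  base <- step_trial_params(noise_sd_force = 0, noise_sd_marker = 0)
  sup <- step_trial_params(noise_sd_force = 0, noise_sd_marker = 0,
                           condition = "supported", suppression_factor = 0.6)
  a <- simulate_step_trial(base, slice, seed = 4)
  b <- simulate_step_trial(sup, slice, seed = 4)
  pk_a <- max(abs(a$traces$f_ml$samples))
  pk_b <- max(abs(b$traces$f_ml$samples))
  expect_equal(pk_b / pk_a, 0.4, tolerance = 1e-6)
  # and the noiseless peak equals the amplitude parameter (the 100 Hz
  # analog-filter emulation leaves the 80 ms plateau intact)
  expect_equal(pk_a, base$fml_amplitude, tolerance = 0.02)
})

test_that("a zero marker excursion leaves the step undetectable", {
  p <- step_trial_params(marker_excursion = 0, noise_sd_marker = 0)
  rec <- simulate_step_trial(p, slice, seed = 2)
  res <- analyze_step_recording(rec, foot_length_cm = 25)
  expect_false(res$valid)
  expect_match(res$reason, "no step onset")
})

test_that("the online trigger reproduces the offline threshold search", {
  # noiseless 50 % drop: the floored SD makes the threshold reachable
  # and the trigger lands on the first sample at or after the drop
  p <- supine_trial_params(noise_sd = 0, lift_drop_fraction = 0.5)
  rec <- simulate_supine_trial(p, slice, seed = 6)
  cal <- c(slice$cross_onset, slice$prepare_onset)
  ev <- run_acquisition_loop(rec, cal)
  t_star <- rec$ground_truth$true_lift_onset
  trig <- ev$onset[ev$trial_type == "trigger"]
  expect_identical(trig, offline_trigger_time(rec, cal))
  expect_gte(trig, t_star)
  # the drop crosses m - 20*s_floor within a few ms of lift onset
  expect_lt(trig, t_star + 3 / p$rate_hz)
  # relax command exactly 500 ms later (1 ms precision contract)
  relax <- ev$onset[ev$trial_type == "relax_cmd"]
  expect_equal(relax, trig + 0.5, tolerance = 1e-9)

  # constant trace: no trigger, no relax command
  flat <- trial_recording(
    list(right_foot = force_trace(rep(10, 416), 32, "right_foot")),
    events = rec$events)
  expect_identical(nrow(run_acquisition_loop(flat, cal)), 0L)

  # undersized calibration window
  expect_error(run_acquisition_loop(rec, c(5.95, 6.0)), "fewer than 5")
})

test_that("online and offline trigger agree exactly across noisy trials", {
  set.seed(31)
  for (i in 1:40) {
    p <- supine_trial_params(noise_sd = runif(1, 0.05, 0.5),
                             lift_drop_fraction = runif(1, 0.3, 0.9))
    rec <- simulate_supine_trial(p, slice, seed = 1000 + i)
    cal <- c(slice$cross_onset, slice$prepare_onset)
    ev <- run_acquisition_loop(rec, cal)
    online <- if (nrow(ev) > 0) ev$onset[ev$trial_type == "trigger"] else NA_real_
    expect_identical(online, offline_trigger_time(rec, cal))
  }
})

test_that("higher suppression never increases the detected APA", {
  # monotonicity under a shared noise realization
  prev <- Inf
  for (s in c(0, 0.3, 0.6, 0.9)) {
    cond <- if (s > 0) "supported" else "unsupported"
    rec <- simulate_supine_trial(
      supine_trial_params(condition = cond, suppression_factor = s),
      slice, seed = 77)
    res <- analyze_supine_recording(rec)
    if (res$valid) {
      expect_lte(res$apa_peak, prev + 1e-9)
      prev <- res$apa_peak
    }
  }
})
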