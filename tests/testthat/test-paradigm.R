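test_that("grid durations follow the truncated-Poisson law", {
  set.seed(101)
  # degenerate rate: all mass at the grid origin
  expect_true(all(sample_grid_duration(c(1, 3), 0.5, 1e-9, 200) == 1.0))

  # support check on the ISI grid
  d <- sample_grid_duration(c(5.5, 8.5), 0.5, 1.5, 2000)
  expect_true(all(d %in% seq(5.5, 8.5, by = 0.5)))

  # empirical pmf matches the closed-form truncated-Poisson pmf
  n <- 1e5
  lambda <- 1.5
  d <- sample_grid_duration(c(1, 3), 0.5, lambda, n)
  # oracle: renormalized Poisson mass over grid indices 0..4
  p_oracle <- dpois(0:4, lambda) / sum(dpois(0:4, lambda))
  emp <- tabulate(match(d, seq(1, 3, by = 0.5)), nbins = 5) / n
  se <- sqrt(p_oracle * (1 - p_oracle) / n)
  expect_true(all(abs(emp - p_oracle) < 3 * se))

  expect_error(sample_grid_duration(c(1, 3), 0.7, 1.5), "divide")
})

test_that("schedules satisfy their invariants and are seed-deterministic", {
  cfg <- paradigm_config()
  sched <- build_schedule(cfg, seed = 7)
  ev <- sched$events
  expect_identical(sum(ev$trial_type == "prepare_circle"), 30L)
  expect_identical(sum(ev$trial_type == "go_circle"), 30L)
  prep <- ev$duration[ev$trial_type == "prepare_circle"]
  isi <- ev$duration[ev$trial_type == "cross"]
  expect_true(all(prep %in% seq(1, 3, by = 0.5)))
  expect_true(all(isi %in% seq(5.5, 8.5, by = 0.5)))
  expect_true(all(ev$duration[ev$trial_type == "go_circle"] <= 5))
  # events tile the run: onsets strictly increase, back to back
  expect_true(all(diff(ev$onset) > 0))
  expect_equal(ev$onset[-1], head(ev$onset + ev$duration, -1))
  # analytic bounds on the planned run length
  expect_gte(sched$total_duration, 30 * (1 + 5.5 + 0))
  expect_lte(sched$total_duration, 30 * (3 + 8.5 + 5))

  expect_identical(build_schedule(cfg, seed = 7)$events, sched$events)

  # different seeds virtually always differ in at least one duration
  for (s in 1:10) {
    a <- build_schedule(cfg, seed = s)$events$duration
    b <- build_schedule(cfg, seed = s + 1000)$events$duration
    expect_false(identical(a, b))
  }
})

test_that("random configurations keep durations on their grids", {
  set.seed(55)
  for (i in 1:20) {
    lam <- runif(1, 0.2, 5)
    k1 <- sample(2:6, 1)
    lo <- sample(seq(0.5, 4, by = 0.5), 1)
    cfg <- paradigm_config(n_trials = 5, poisson_rate = lam,
                           prepare_range = c(lo, lo + 0.5 * k1))
    ev <- build_schedule(cfg)$events
    prep <- ev$duration[ev$trial_type == "prepare_circle"]
    expect_true(all(prep %in% seq(lo, lo + 0.5 * k1, by = 0.5)))
  }
})

test_that("counterbalancing splits subjects as evenly as possible", {
  cb <- counterbalance(1:10, seed = 3)
  expect_identical(unname(table(cb$assignment)["open_is_prepare"]), 5L)
  cb1 <- counterbalance("s1", seed = 3)
  expect_identical(cb1$assignment, "open_is_prepare")
  cb7 <- counterbalance(1:7, seed = 9)
  expect_setequal(unname(table(cb7$assignment)), c(4L, 3L))
  expect_identical(counterbalance(1:8, seed = 12),
                   counterbalance(1:8, seed = 12))
})
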