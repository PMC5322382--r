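test_that("descriptives reproduce the cohort table's printed summaries", {
  subj <- pd_cohort_table()
  d <- descriptives(subj$updrs_motor)
  expect_equal(round(d$mean, 2), 32.25)
  expect_equal(round(d$sd, 2), 7.63)
  d <- descriptives(subj$age)
  expect_equal(round(d$mean, 2), 67.50)
  expect_equal(round(d$sd, 2), 4.66)

  d1 <- descriptives(5)
  expect_equal(d1$mean, 5)
  expect_true(is.na(d1$sd))
  expect_error(descriptives(numeric(0)), "empty")
})

test_that("exact signed-rank p-values equal sign-flip enumeration", {
  # all-positive differences, n = 5: one-sided p = 1/32
  w <- wilcoxon_exact(c(0.3, 1.2, 0.7, 2.2, 0.1))
  expect_equal(w$statistic, 15)
  expect_equal(w$p_greater, 1 / 32)
  expect_equal(w$p_exact, 2 / 32)

  # antisymmetric differences sit at the center of the distribution
  w <- wilcoxon_exact(c(-2, -1, 1, 2))
  expect_equal(w$p_exact, 1)

  # zeros are dropped; all-zero input is degenerate with p = 1
  expect_identical(wilcoxon_exact(c(0, 0, 0))$p_exact, 1)
  expect_identical(wilcoxon_exact(c(0, 0, 3, -1))$n_used, 2L)

  # random instances, including ties, against the brute-force oracle
  set.seed(61)
  for (i in 1:15) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n, sd = 2), sample(0:1, 1))
    d <- d[d != 0]
    if (length(d) < 2) next
    got <- wilcoxon_exact(d)
    want <- brute_signed_rank(d)
    expect_equal(got$statistic, want$W)
    expect_equal(got$p_exact, want$p_two, tolerance = 1e-12)
    expect_equal(got$p_less, want$p_less, tolerance = 1e-12)
  }

  # untied instances also agree with the reference implementation
  set.seed(62)
  d <- rnorm(10)
  expect_equal(wilcoxon_exact(d)$p_exact,
               wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("exact Mann-Whitney p-values equal subset enumeration", {
  # fully separated groups of 4: U = 0, one-sided p = 1/choose(8,4)
  a <- c(1, 2, 3, 4); b <- c(10, 11, 12, 13)
  mw <- mannwhitney_exact(a, b)
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_less, 1 / 70)

  # identical groups: center of the distribution, p near 1
  mw <- mannwhitney_exact(c(5, 6, 7), c(5, 6, 7))
  expect_gt(mw$p_exact, 0.9)

  # random instances (with and without ties) against the oracle
  set.seed(63)
  for (i in 1:12) {
    nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    a <- round(rnorm(nA, sd = 2), 1); b <- round(rnorm(nB, 1, 2), 1)
    got <- mannwhitney_exact(a, b)
    want <- brute_mannwhitney(a, b)
    expect_equal(got$statistic, want$U)
    expect_equal(got$p_exact, want$p_two, tolerance = 1e-12)
  }

  # untied case against the reference implementation
  a <- rnorm(10); b <- rnorm(8, 0.5)
  expect_equal(mannwhitney_exact(a, b)$p_exact,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)

  expect_error(mannwhitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("Spearman correlation honors monotone transforms and ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_rank(x, exp(x), method = "tapprox")$statistic, 1)
  expect_equal(spearman_rank(x, -x^3, method = "tapprox")$statistic, -1)
  expect_error(spearman_rank(x, rep(2, 7)), "constant")

  # n = 8, untied: exact enumeration equals the reference exact p
  set.seed(64)
  x <- rnorm(8); y <- 0.8 * x + rnorm(8, sd = 0.6)
  got <- spearman_rank(x, y, method = "exact")
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(got$statistic, unname(ref$estimate))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  # and equals the recursive enumeration oracle at n = 6
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(spearman_rank(x, y, method = "exact")$p,
               brute_spearman_p(x, y), tolerance = 1e-12)

  # sampled permutation p agrees with exact within Monte-Carlo error
  set.seed(65)
  x <- rnorm(8); y <- x + rnorm(8, sd = 2)
  p_exact <- spearman_rank(x, y, method = "exact")$p
  p_samp <- spearman_rank(x, y, method = "sampled", n_perm = 20000)$p
  expect_lt(abs(p_samp - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 20000) + 1e-4)
})

test_that("normal approximations track the exact tests at moderate n", {
  set.seed(66)
  d <- rnorm(15, 0.4)
  w <- wilcoxon_exact(d)
  expect_lt(abs(w$p_normal - w$p_exact), 0.05)
  a <- rnorm(12); b <- rnorm(10, 0.8)
  mw <- mannwhitney_exact(a, b)
  expect_lt(abs(mw$p_normal - mw$p_exact), 0.05)
})
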