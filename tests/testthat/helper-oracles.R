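# Independent brute-force oracles used to check the package's exact
# tests and online detectors.  These deliberately share no code with the
# implementation: plain loops and full enumerations.

# signed-rank test by explicit enumeration of all 2^m sign assignments
brute_signed_rank <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(list(W = 0, p_less = 1, p_greater = 1, p_two = 1))
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  Ws <- numeric(2^m)
  for (code in 0:(2^m - 1)) {
    pos <- bitwAnd(code, bitwShiftL(1L, 0:(m - 1))) > 0
    Ws[code + 1] <- sum(r[pos])
  }
  p_less <- mean(Ws <= W_obs + 1e-9)
  p_greater <- mean(Ws >= W_obs - 1e-9)
  list(W = W_obs, p_less = p_less, p_greater = p_greater,
       p_two = min(1, 2 * min(p_less, p_greater)))
}

# Mann-Whitney by explicit enumeration of all group-A index subsets
brute_mannwhitney <- function(a, b) {
  nA <- length(a)
  n <- nA + length(b)
  r <- rank(c(a, b))
  W_obs <- sum(r[seq_len(nA)])
  subsets <- utils::combn(n, nA)
  Ws <- apply(subsets, 2, function(ii) sum(r[ii]))
  p_less <- mean(Ws <= W_obs + 1e-9)
  p_greater <- mean(Ws >= W_obs - 1e-9)
  list(U = W_obs - nA * (nA + 1) / 2,
       p_less = p_less, p_greater = p_greater,
       p_two = min(1, 2 * min(p_less, p_greater)))
}

# all permutations of 1..n by simple recursion (independent of
# pracma::perms, which the implementation uses)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

brute_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rs_obs <- stats::cor(rx, ry)
  pm <- all_perms(length(x))
  rs_all <- apply(pm, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rs_all) >= abs(rs_obs) - 1e-12)
}

# offline full-scan threshold search: the oracle the online trigger
# loop must reproduce sample for sample
offline_trigger_time <- function(recording, calibration_window,
                                 channel = "right_foot", k_sd = 20,
                                 sd_floor_frac = 0.005) {
  tr <- recording$traces[[channel]]
  tt <- trace_times(tr)
  ci <- which(tt >= calibration_window[1] & tt < calibration_window[2])
  m <- mean(tr$samples[ci])
  s <- max(stats::sd(tr$samples[ci]), sd_floor_frac * abs(m))
  ev <- recording$events
  go <- ev[ev$trial_type == "go_circle", ]
  hits <- which(tt >= go$onset[1] & tt < go$onset[1] + go$duration[1] &
                  tr$samples < m - k_sd * s)
  if (length(hits) == 0) NA_real_ else tt[hits[1]]
}

# brute-force scan for the first hold-length run beyond a threshold
brute_crossing_time <- function(trace, window, m, s, k_sd, direction, hold) {
  tt <- trace_times(trace)
  idx <- which(tt >= window[1] & tt < window[2])
  thr <- if (direction == "above") m + k_sd * s else m - k_sd * s
  for (j in seq_along(idx)) {
    if (j + hold - 1 > length(idx)) break
    seg <- trace$samples[idx[j:(j + hold - 1)]]
    ok <- if (direction == "above") all(seg > thr) else all(seg < thr)
    if (ok) return(tt[idx[j]])
  }
  NA_real_
}

# one-trial schedule slice without going through the paradigm module
make_slice <- function(cross = 0, prepare = 6, go = 8, go_max = 5) {
  list(cross_onset = cross, prepare_onset = prepare, go_onset = go,
       go_max = go_max, trial_end = go + go_max)
}
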