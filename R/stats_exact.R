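#' Descriptive statistics
#'
#' Mean, SD (n-1 denominator), standard error, minimum and maximum.
#' SD and SE are \code{NA} at n = 1 (undefined with the n-1
#' denominator).
#'
#' @param values numeric vector (non-empty, finite).
#' @return list with \code{n}, \code{mean}, \code{sd}, \code{se},
#'   \code{min}, \code{max}.
#' @export
descriptives <- function(values) {
  if (length(values) < 1L) stop("descriptives: empty input")
  if (any(!is.finite(values))) stop("descriptives: non-finite values")
  n <- length(values)
  s <- if (n >= 2) stats::sd(values) else NA_real_
  list(n = n, mean = mean(values), sd = s,
       se = if (n >= 2) s / sqrt(n) else NA_real_,
       min = min(values), max = max(values))
}

# distribution of the signed-rank sum over all 2^m sign assignments,
# on doubled (integer) midranks; returns counts indexed by doubled sum 0..S
.signed_rank_counts <- function(ranks2) {
  S <- sum(ranks2)
  f <- numeric(S + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(S + 1)] <- g[(r + 1):(S + 1)] + f[1:(S + 1 - r)]
    f <- g
  }
  f
}

#' Exact Wilcoxon signed-rank test
#'
#' Signed-rank statistic W (sum of ranks of positive differences, with
#' midranks for tied absolute differences) and its exact p-value from
#' the full distribution over all 2^m sign assignments.  Zero
#' differences are dropped before ranking (Wilcoxon's original rule);
#' if every difference is zero the test is degenerate and p = 1.  A
#' normal-approximation z (tie-corrected variance) is also reported.
#' Two-sided p doubles the smaller tail, capped at 1.
#'
#' @param x numeric vector: condition-A values, or differences if
#'   \code{y} is \code{NULL}.
#' @param y optional numeric vector of paired condition-B values.
#' @return list of class \code{exact_test}: \code{statistic} (W),
#'   \code{n_used}, \code{p_exact} (two-sided), \code{p_less},
#'   \code{p_greater}, \code{z}, \code{p_normal}.
#' @export
wilcoxon_exact <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  if (any(!is.finite(d))) stop("wilcoxon_exact: non-finite differences")
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    res <- list(statistic = 0, n_used = 0L, p_exact = 1,
                p_less = 1, p_greater = 1, z = 0, p_normal = 1,
                method = "Wilcoxon signed-rank (degenerate: all zero)")
    class(res) <- "exact_test"
    return(res)
  }
  if (m > 25)
    stop("wilcoxon_exact: exact enumeration limited to 25 non-zero ",
         "differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  counts <- .signed_rank_counts(r2)
  total <- 2^m
  W2 <- round(2 * W)
  sums <- seq_along(counts) - 1
  p_less <- sum(counts[sums <= W2]) / total
  p_greater <- sum(counts[sums >= W2]) / total
  mu <- m * (m + 1) / 4
  sigma <- sqrt(sum(r^2) / 4)
  z <- if (sigma > 0) (W - mu) / sigma else 0
  res <- list(statistic = W, n_used = m,
              p_exact = min(1, 2 * min(p_less, p_greater)),
              p_less = p_less, p_greater = p_greater,
              z = z, p_normal = 2 * stats::pnorm(-abs(z)),
              method = "Wilcoxon signed-rank, exact (2^m sign assignments)")
  class(res) <- "exact_test"
  res
}

# counts of subsets of size k with given doubled-rank sum, via the
# standard size-by-sum dynamic program over the observed midranks
.ranksum_counts <- function(ranks2, k) {
  S <- sum(ranks2)
  dp <- matrix(0, nrow = k + 1, ncol = S + 1)
  dp[1, 1] <- 1
  for (r in ranks2) {
    for (kk in k:1) {
      nz <- which(dp[kk, ] > 0)
      if (length(nz) > 0)
        dp[kk + 1, nz + r] <- dp[kk + 1, nz + r] + dp[kk, nz]
    }
  }
  dp[k + 1, ]
}

#' Exact Mann-Whitney U test
#'
#' U statistic from midranks and its exact p-value from the permutation
#' distribution of the group-A rank sum over all
#' \code{choose(nA + nB, nA)} group assignments of the observed
#' (possibly tied) ranks — the exact null distribution whether or not
#' ties are present.  A tie-corrected normal z is also reported.
#' Two-sided p doubles the smaller tail, capped at 1.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list of class \code{exact_test}: \code{statistic} (U for
#'   group a), \code{U_min}, \code{p_exact} (two-sided), \code{p_less},
#'   \code{p_greater}, \code{z}, \code{p_normal}.
#' @export
mannwhitney_exact <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    stop("mannwhitney_exact: both groups must be non-empty")
  if (any(!is.finite(c(a, b)))) stop("mannwhitney_exact: non-finite values")
  nA <- length(a); nB <- length(b); n <- nA + nB
  if (n > 40)
    stop("mannwhitney_exact: exact enumeration limited to 40 observations")
  r <- rank(c(a, b))
  WA <- sum(r[seq_len(nA)])
  U <- WA - nA * (nA + 1) / 2
  r2 <- as.integer(round(2 * r))
  counts <- .ranksum_counts(r2, nA)
  total <- choose(n, nA)
  WA2 <- round(2 * WA)
  sums <- seq_along(counts) - 1
  p_less <- sum(counts[sums <= WA2]) / total
  p_greater <- sum(counts[sums >= WA2]) / total
  mu <- nA * (n + 1) / 2
  ties <- table(r)
  sigma2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (WA - mu) / sqrt(sigma2) else 0
  res <- list(statistic = U, U_min = min(U, nA * nB - U), n_a = nA, n_b = nB,
              p_exact = min(1, 2 * min(p_less, p_greater)),
              p_less = p_less, p_greater = p_greater,
              z = z, p_normal = 2 * stats::pnorm(-abs(z)),
              method = "Mann-Whitney U, exact (all group assignments)")
  class(res) <- "exact_test"
  res
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties.  The p-value is exact by
#' enumeration of all n! rank permutations for n <= 8 (method
#' \code{"exact"}), by seeded permutation sampling for larger n
#' (\code{"sampled"}), or from the t approximation
#' (\code{"tapprox"}); \code{"auto"} picks exact for n <= 8 and the t
#' approximation otherwise.  Two-sided throughout.
#'
#' @param x,y numeric vectors of equal length (n >= 3); neither may be
#'   constant.
#' @param method p-value method (see above).
#' @param n_perm permutations for \code{"sampled"}.
#' @return list of class \code{exact_test}: \code{statistic} (r_s),
#'   \code{n}, \code{p}, \code{method}.
#' @export
spearman_rank <- function(x, y,
                          method = c("auto", "exact", "sampled", "tapprox"),
                          n_perm = 10000L) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("spearman_rank: need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("spearman_rank: non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_rank: correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  if (method == "auto") method <- if (n <= 8) "exact" else "tapprox"
  if (method == "exact") {
    if (n > 8) stop("spearman_rank: exact enumeration limited to n <= 8")
    perms <- pracma::perms(seq_len(n))
    rs_all <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rs_all) >= abs(rs) - 1e-12)
  } else if (method == "sampled") {
    rs_all <- vapply(seq_len(n_perm),
                     function(i) stats::cor(rx, sample(ry)), numeric(1))
    p <- (1 + sum(abs(rs_all) >= abs(rs) - 1e-12)) / (n_perm + 1)
  } else {
    tstat <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  res <- list(statistic = rs, n = n, p = p,
              method = paste0("Spearman rank correlation (", method, ")"))
  class(res) <- "exact_test"
  res
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("<%s>\n", x$method))
  if (!is.null(x$p_exact))
    cat(sprintf("  statistic = %.4g, exact two-sided p = %.4g (z = %.3f, normal p = %.4g)\n",
                x$statistic, x$p_exact, x$z, x$p_normal))
  else
    cat(sprintf("  r_s = %.4f (n = %d), two-sided p = %.4g\n",
                x$statistic, x$n, x$p))
  invisible(x)
}
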