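#' Inside/outside-scanner validation battery
#'
#' The full small-sample statistical analysis that validates the
#' scanner task against upright step initiation: per-subject
#' unsupported-minus-supported difference scores for each task, the
#' Spearman correlation between the two tasks' difference scores,
#' paired Wilcoxon contrasts of supported versus unsupported within
#' each task, and (when a clinical score is supplied) Spearman
#' correlations of the score with each task's difference score.
#'
#' @param step_results data.frame with columns \code{subject},
#'   \code{unsupported}, \code{supported} (APA amplitude, N/cm).
#' @param scanner_results same shape (force magnitude, percent).
#' @param clinical optional data.frame with \code{subject} and
#'   \code{updrs}.
#' @param spearman_method p-value method for
#'   \code{\link{spearman_rank}}.
#' @return list of class \code{validation_report}: \code{diffs}
#'   (per-subject difference scores), \code{cross_task} (Spearman,
#'   step vs scanner), \code{wilcoxon_step}, \code{wilcoxon_scanner},
#'   and optionally \code{updrs_step}, \code{updrs_scanner}.
#' @export
validation_analysis <- function(step_results, scanner_results,
                                clinical = NULL,
                                spearman_method = "auto") {
  need <- c("subject", "unsupported", "supported")
  stopifnot(all(need %in% names(step_results)),
            all(need %in% names(scanner_results)))
  if (!setequal(step_results$subject, scanner_results$subject) ||
      anyDuplicated(step_results$subject) ||
      anyDuplicated(scanner_results$subject))
    stop("validation_analysis: subject sets must match across tasks")
  scanner_results <-
    scanner_results[match(step_results$subject, scanner_results$subject), ]
  if (!is.null(clinical)) {
    stopifnot(all(c("subject", "updrs") %in% names(clinical)))
    if (!setequal(clinical$subject, step_results$subject))
      stop("validation_analysis: clinical subjects must match task subjects")
    clinical <- clinical[match(step_results$subject, clinical$subject), ]
  }
  diffs <- data.frame(
    subject = step_results$subject,
    step_diff = step_results$unsupported - step_results$supported,
    scanner_diff = scanner_results$unsupported - scanner_results$supported)
  out <- list(
    diffs = diffs,
    cross_task = spearman_rank(diffs$step_diff, diffs$scanner_diff,
                               method = spearman_method),
    wilcoxon_step = wilcoxon_exact(step_results$unsupported,
                                   step_results$supported),
    wilcoxon_scanner = wilcoxon_exact(scanner_results$unsupported,
                                      scanner_results$supported))
  if (!is.null(clinical)) {
    out$updrs_step <- spearman_rank(clinical$updrs, diffs$step_diff,
                                    method = spearman_method)
    out$updrs_scanner <- spearman_rank(clinical$updrs, diffs$scanner_diff,
                                       method = spearman_method)
  }
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  n <- nrow(x$diffs)
  cat(sprintf("<validation_report> %d matched subjects\n", n))
  cat(sprintf("  cross-task r_s = %.3f (p = %.4g)\n",
              x$cross_task$statistic, x$cross_task$p))
  cat(sprintf("  step: Wilcoxon W = %.1f, exact p = %.4g\n",
              x$wilcoxon_step$statistic, x$wilcoxon_step$p_exact))
  cat(sprintf("  scanner: Wilcoxon W = %.1f, exact p = %.4g\n",
              x$wilcoxon_scanner$statistic, x$wilcoxon_scanner$p_exact))
  if (!is.null(x$updrs_step))
    cat(sprintf("  UPDRS vs step r_s = %.3f (p = %.4g); vs scanner r_s = %.3f (p = %.4g)\n",
                x$updrs_step$statistic, x$updrs_step$p,
                x$updrs_scanner$statistic, x$updrs_scanner$p))
  invisible(x)
}
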