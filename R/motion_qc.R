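#' Head-motion displacement summary
#'
#' Per-volume displacement is the Euclidean norm of the three head
#' translations relative to a reference volume — the combined
#' medio-lateral, antero-posterior and superior-inferior motion.
#' Rotations are carried in the series but excluded from the criterion.
#' A run passes quality control when its maximum displacement stays
#' below 1 mm, the conventional limit for a 3 mm EPI voxel.
#'
#' @param motion a \code{motion_series} (>= 2 volumes).
#' @param reference \code{"first"} (default) or \code{"middle"} volume.
#' @return list of class \code{motion_summary}:
#'   \code{mean_abs_displacement}, \code{max_abs_displacement},
#'   \code{per_volume_displacement} (mm), \code{pass_1mm},
#'   \code{reference}.
#' @export
mean_displacement <- function(motion, reference = c("first", "middle")) {
  stopifnot(inherits(motion, "motion_series"))
  reference <- match.arg(reference)
  if (motion$n_volumes < 2L)
    stop("mean_displacement: need at least 2 volumes")
  trans <- motion$params[, 4:6, drop = FALSE]
  ref_row <- if (reference == "first") 1L
             else as.integer(ceiling(motion$n_volumes / 2))
  d <- sweep(trans, 2, trans[ref_row, ])
  disp <- sqrt(rowSums(d^2))
  structure(list(mean_abs_displacement = mean(disp),
                 max_abs_displacement = max(disp),
                 per_volume_displacement = disp,
                 pass_1mm = max(disp) < 1.0,
                 reference = reference),
            class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf(
    "<motion_summary> mean %.3f mm, max %.3f mm (reference: %s) — %s\n",
    x$mean_abs_displacement, x$max_abs_displacement, x$reference,
    if (x$pass_1mm) "PASS (< 1 mm)" else "FAIL (>= 1 mm)"))
  invisible(x)
}

#' Group head-motion QC report
#'
#' Summarizes mean displacement across runs the way a results paragraph
#' reports it: per-group mean, standard error and range of the
#' per-run mean absolute displacement, plus the 1 mm pass count.
#'
#' @param summaries list of \code{motion_summary} objects.
#' @param group optional character vector (one label per summary, e.g.
#'   subject group and condition); a single group is assumed if omitted.
#' @return data.frame with one row per group: \code{n}, \code{mean_mm},
#'   \code{se_mm}, \code{min_mm}, \code{max_mm}, \code{n_pass_1mm}.
#' @export
qc_report <- function(summaries, group = NULL) {
  if (length(summaries) < 1L) stop("qc_report: no summaries")
  ok <- vapply(summaries, inherits, logical(1), "motion_summary")
  if (!all(ok)) stop("qc_report: inputs must be motion_summary objects")
  if (is.null(group)) group <- rep("all", length(summaries))
  stopifnot(length(group) == length(summaries))
  means <- vapply(summaries, `[[`, numeric(1), "mean_abs_displacement")
  pass <- vapply(summaries, `[[`, logical(1), "pass_1mm")
  out <- lapply(split(seq_along(summaries), group), function(ii) {
    v <- means[ii]
    data.frame(group = group[ii[1]], n = length(v), mean_mm = mean(v),
               se_mm = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               min_mm = min(v), max_mm = max(v),
               n_pass_1mm = sum(pass[ii]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
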