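#' Rigid-body motion parameter series
#'
#' Per-volume 6-parameter head-motion estimates: three rotations (rad)
#' and three translations (mm).  The column order in source files varies
#' by tool; the \code{dialect} tag declares which half comes first.
#'
#' @param params numeric matrix, one row per volume, exactly 6 columns,
#'   already in rotations-then-translations order.
#' @return an object of class \code{motion_series}.
#' @export
motion_series <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion_series: expected 6 columns")
  if (nrow(params) < 1L) stop("motion_series: no volumes")
  if (any(!is.finite(params))) stop("motion_series: non-finite values")
  colnames(params) <- c("rot_x", "rot_y", "rot_z",
                        "trans_x", "trans_y", "trans_z")
  structure(list(params = params, n_volumes = nrow(params)),
            class = "motion_series")
}

#' @export
print.motion_series <- function(x, ...) {
  cat(sprintf("<motion_series> %d volumes (3 rotations rad, 3 translations mm)\n",
              x$n_volumes))
  invisible(x)
}

#' Read a 6-column motion parameter file
#'
#' Whitespace-separated numeric text, one row per volume.  The default
#' dialect is rotations-first (radians) then translations (mm), the
#' common 6-column convention; \code{"translations_first"} swaps the
#' halves on read.
#'
#' @param path file path.
#' @param dialect \code{"rotations_first"} (default) or
#'   \code{"translations_first"}.
#' @return a \code{motion_series} in rotations-first internal order.
#' @export
read_motion_params <- function(path,
                               dialect = c("rotations_first",
                                           "translations_first")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) stop("motion parameters: empty file: ", path)
  parts <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop(sprintf("motion parameters: line %d has %d columns, expected 6",
                 keep[which(nf != 6L)[1]], nf[which(nf != 6L)[1]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 6L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop(sprintf("motion parameters: non-numeric value at line %d", keep[bad]))
  }
  if (dialect == "translations_first") m <- m[, c(4:6, 1:3), drop = FALSE]
  motion_series(m)
}
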