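#' Read a subject demographics/clinical table
#'
#' CSV with header; one row per subject.  Required columns: \code{id},
#' \code{age} (y), \code{sex}, \code{weight} (kg), \code{height} (m).
#' Optional clinical columns: \code{disease_duration} (y),
#' \code{updrs_motor} (UPDRS part III motor score), \code{dled_mg}
#' (daily levodopa-equivalent dose, mg), \code{side_affected},
#' \code{foot_length_cm}.  Missing optional values are allowed (empty
#' cells become \code{NA}); non-numeric age or weight is an error.
#' \code{foot_length_cm} must be positive wherever APA amplitude
#' normalization is later requested — \code{\link{compute_step_apa}}
#' enforces that at the point of use.
#'
#' @param path CSV file path.
#' @return a \code{data.frame} of class \code{subject_table}.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "weight", "height")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("demographics: missing required columns: ",
         paste(miss, collapse = ", "))
  num_req <- c("age", "weight", "height")
  num_opt <- c("disease_duration", "updrs_motor", "dled_mg", "foot_length_cm")
  for (cl in num_req) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (nrow(df) > 0 && (anyNA(v) || any(!is.finite(v))))
      stop("demographics: non-numeric value in required column '", cl, "'")
    df[[cl]] <- v
  }
  for (cl in intersect(num_opt, names(df))) {
    orig <- df[[cl]]
    v <- suppressWarnings(as.numeric(orig))
    mangled <- !is.na(orig) & nzchar(trimws(as.character(orig))) & is.na(v)
    if (any(mangled))
      stop("demographics: non-numeric value in column '", cl, "'")
    df[[cl]] <- v
  }
  class(df) <- c("subject_table", "data.frame")
  df
}

#' Packaged 8-patient cohort table
#'
#' The Parkinson's disease cohort table shipped with the package
#' (age, sex, weight, height, disease duration, UPDRS motor score,
#' daily levodopa-equivalent dose, most-affected side), used by the
#' cohort-descriptives examples and the acceptance script.
#'
#' @return a \code{subject_table} with 8 rows.
#' @export
pd_cohort_table <- function() {
  read_demographics(system.file("extdata", "table1_demographics.csv",
                                package = "fmsapa", mustWork = TRUE))
}

#' Cohort descriptive summary
#'
#' Mean, SD (n-1), SE, min and max for each numeric column of a subject
#' table, in the Mean (+/- SD) style of a demographics table.
#'
#' @param subjects a \code{subject_table}.
#' @param columns numeric columns to summarize; defaults to all numeric
#'   columns present.
#' @return a \code{data.frame} with one row per column.
#' @export
cohort_summary <- function(subjects,
                           columns = c("age", "weight", "height",
                                       "disease_duration", "updrs_motor",
                                       "dled_mg")) {
  columns <- intersect(columns, names(subjects))
  columns <- columns[vapply(subjects[columns], is.numeric, logical(1))]
  rows <- lapply(columns, function(cl) {
    v <- subjects[[cl]]
    v <- v[!is.na(v)]
    d <- descriptives(v)
    data.frame(variable = cl, n = d$n, mean = d$mean, sd = d$sd,
               se = d$se, min = d$min, max = d$max)
  })
  do.call(rbind, rows)
}
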